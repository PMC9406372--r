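# Evaluation: confusion matrices, classification reports, ROC/AUC,
# consistency studies and gradient saliency.

#' Confusion matrix
#'
#' Rows index the true class, columns the predicted class; entry (i, j)
#' counts images of true class i predicted as class j.
#'
#' @param truth,pred equal-length label vectors (factors or characters).
#'   Levels default to `bethesda_classes()` unless the inputs carry their
#'   own factor levels.
#' @param levels optional explicit class levels.
#' @return integer matrix with class dimnames.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (length(truth) != length(pred))
    stop("contract error: truth and pred lengths differ")
  if (is.null(levels)) {
    levels <- if (is.factor(truth)) levels(truth)
      else if (all(unique(c(as.character(truth), as.character(pred))) %in%
                   bethesda_classes())) bethesda_classes()
      else sort(unique(c(as.character(truth), as.character(pred))))
  }
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(pred), levels = levels)
  cm <- table(truth = t_f, pred = p_f)
  matrix(as.integer(cm), nrow = length(levels),
         dimnames = list(truth = levels, pred = levels))
}

#' Classification report
#'
#' Computes accuracy (trace / total), per-class one-vs-rest precision,
#' recall and F1 plus their support-weighted and macro averages, and the
#' macro-averaged one-vs-rest false-positive and false-negative rates.
#' Support-weighted recall equals accuracy by construction. Classes with
#' zero support (or zero predicted positives) contribute a 0 metric with a
#' warning rather than NaN.
#'
#' @param cm a square confusion matrix (rows = truth).
#' @return list of class `metrics_report`: `accuracy`, `per_class` (data
#'   frame), `precision`, `recall`, `f1` (weighted), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `fpr`, `fnr`, `support`.
#' @export
classification_report <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  k <- nrow(cm)
  support <- rowSums(cm)
  accuracy <- if (total > 0) sum(diag(cm)) / total else 0
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) warning("zero denominator in ", what, "; reporting 0")
    out <- ifelse(bad, 0, num / den)
    out
  }
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  fpr <- safe_div(fp, fp + tn, "FPR")
  fnr <- safe_div(fn, fn + tp, "FNR")
  wt <- if (total > 0) support / total else rep(0, k)
  per_class <- data.frame(class = rownames(cm) %||% as.character(seq_len(k)),
                          support = as.integer(support),
                          precision = precision, recall = recall, f1 = f1,
                          fpr = fpr, fnr = fnr, row.names = NULL)
  structure(list(
    accuracy = accuracy,
    per_class = per_class,
    precision = sum(wt * precision), recall = sum(wt * recall),
    f1 = sum(wt * f1),
    macro_precision = mean(precision), macro_recall = mean(recall),
    macro_f1 = mean(f1),
    fpr = mean(fpr), fnr = mean(fnr),
    support = support
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | weighted P %.4f R %.4f F1 %.4f | FPR %.4f FNR %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$fpr, x$fnr))
  print(x$per_class, digits = 4)
  invisible(x)
}

binary_auc <- function(pos, score) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("undefined AUC: single-class truth")
  r <- rank(score)                     # average ranks give ties 0.5 credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(pos, score) {
  ths <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- vapply(ths, function(t) mean(score[pos] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(score[!pos] >= t), numeric(1))
  data.frame(threshold = ths, fpr = fpr, tpr = tpr)
}

#' ROC curves and AUC
#'
#' One-vs-rest ROC analysis. In the multiclass scheme each Bethesda class
#' is in turn treated as positive with its score column; the macro-average
#' of the per-class AUCs is reported. In the binary scheme labels are first
#' collapsed with [binarize_labels()] and the positive score is the summed
#' HSIL + SCC score. Tied scores receive 0.5 credit (average ranks /
#' trapezoidal rule).
#'
#' @param truth labels.
#' @param score_vectors n x 4 score matrix (or n x 2, or a vector of
#'   positive-class scores for the binary scheme).
#' @param scheme `"multiclass_ovr"` or `"binary"`.
#' @return list with `auc` (macro for multiclass), `per_class` named AUC
#'   vector, and `curves` (list of ROC point data frames).
#' @export
roc_auc <- function(truth, score_vectors, scheme = c("multiclass_ovr",
                                                     "binary")) {
  scheme <- match.arg(scheme)
  if (scheme == "binary") {
    bt <- if (is.factor(truth) && nlevels(truth) == 2) truth
    else if (all(as.character(truth) %in% c("negative", "positive")))
      factor(as.character(truth), levels = c("negative", "positive"))
    else binarize_labels(truth)
    score <- if (is.matrix(score_vectors) && ncol(score_vectors) == 4)
      rowSums(score_vectors[, 3:4, drop = FALSE])
    else if (is.matrix(score_vectors)) score_vectors[, ncol(score_vectors)]
    else as.numeric(score_vectors)
    if (any(!is.finite(score))) stop("scores must be finite")
    pos <- bt == levels(bt)[2]    # second level is the positive class
    auc <- binary_auc(pos, score)
    return(list(auc = auc, per_class = c(positive = auc),
                curves = list(positive = roc_points(pos, score))))
  }
  f <- bethesda_factor(truth)
  sc <- as.matrix(score_vectors)
  if (any(!is.finite(sc))) stop("scores must be finite")
  stopifnot(ncol(sc) == 4, nrow(sc) == length(f))
  lv <- bethesda_classes()
  aucs <- numeric(4); curves <- list()
  for (k in 1:4) {
    pos <- as.integer(f) == k
    aucs[k] <- binary_auc(pos, sc[, k])
    curves[[lv[k]]] <- roc_points(pos, sc[, k])
  }
  names(aucs) <- lv
  list(auc = mean(aucs), per_class = aucs, curves = curves)
}

#' Multi-run consistency study
#'
#' Re-trains a model from scratch once per seed and evaluates each run on
#' the same fixed test data, summarizing the run-to-run spread of accuracy
#' with the mean, sample standard deviation (divisor n - 1), maximum and
#' minimum. Failed runs are flagged and excluded from the summary rather
#' than aborting the study.
#'
#' @param train_callable function(seed) returning a test-set accuracy in
#'   `[0, 1]`.
#' @param n_runs number of runs (>= 2) when `seeds` is not given.
#' @param seeds explicit seeds (overrides `n_runs`).
#' @return list of class `run_summary`: `accuracies`, `mean`, `sd`, `max`,
#'   `min`, `failures` (logical vector).
#' @export
consistency_study <- function(train_callable, n_runs = 5, seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  if (length(seeds) < 2) stop("consistency study needs at least 2 runs")
  acc <- rep(NA_real_, length(seeds))
  fail <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    r <- tryCatch(train_callable(seeds[i]), error = function(e) e)
    if (inherits(r, "error")) fail[i] <- TRUE else acc[i] <- as.numeric(r)
  }
  ok <- acc[!fail]
  structure(list(
    accuracies = acc, failures = fail,
    mean = mean(ok), sd = stats::sd(ok), max = max(ok), min = min(ok)
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("runs %d (failed %d): mean %.4f sd %.4f max %.4f min %.4f\n",
              length(x$accuracies), sum(x$failures), x$mean, x$sd,
              x$max, x$min))
  invisible(x)
}

#' Gradient saliency map
#'
#' Backpropagates the selected class score to the input pixels and reports,
#' per pixel, the maximum over colour channels of the absolute gradient,
#' min-max normalized to `[0, 1]` (an all-zero gradient stays all-zero).
#' High values mark pixels whose perturbation most changes the class score.
#'
#' @param model a differentiable `cyto_model` classifier.
#' @param image single h x w x 3 image (resized to the model input).
#' @param class_index class whose score is differentiated (1-based; default
#'   the predicted class).
#' @return h x w saliency matrix in `[0, 1]` matching the model's input
#'   spatial dimensions.
#' @export
gradient_saliency <- function(model, image, class_index = NULL) {
  if (length(model$input_shape) != 3)
    stop("capability error: saliency needs a spatial input model")
  x <- resize_image(unclass_image(image),
                    model$input_shape[1], model$input_shape[2])
  xb <- array(x, dim = c(dim(x), 1))
  fw <- model_forward(model, xb, training = FALSE, want_cache = TRUE)
  scores <- fw$out
  if (is.null(class_index)) class_index <- which.max(scores[1, ])
  dout <- matrix(0, 1, ncol(scores))
  dout[1, class_index] <- 1
  dx <- model_backward(model, fw$caches, dout)$dx[, , , 1, drop = FALSE]
  sal <- pmax(abs(dx[, , 1, 1]), abs(dx[, , 2, 1]), abs(dx[, , 3, 1]))
  rng <- range(sal)
  if (rng[2] - rng[1] < .Machine$double.eps) return(sal * 0)
  (sal - rng[1]) / (rng[2] - rng[1])
}
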