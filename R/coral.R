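# CORAL (correlation alignment) unsupervised domain adaptation.

#' Batch covariance matrix
#'
#' The d x d sample covariance of an n x d activation batch, computed as
#' `C = (D'D - (1/n) (1'D)'(1'D)) / (n - 1)` where `1` is the all-ones
#' column vector. Symmetric and positive semi-definite by construction.
#'
#' @param D numeric n x d matrix (rows = examples).
#' @return d x d covariance matrix.
#' @export
batch_covariance <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("degenerate batch: covariance needs at least 2 rows")
  s <- colSums(D)                      # = 1'D
  C <- (crossprod(D) - tcrossprod(s) / n) / (n - 1)
  (C + t(C)) / 2
}

#' CORAL loss
#'
#' Squared Frobenius distance between source and target batch covariances,
#' scaled by `1 / (4 d^2)`:
#' `l_CORAL = ||C_S - C_T||_F^2 / (4 d^2)`. Nonnegative, zero iff the
#' covariances coincide, symmetric in its arguments and invariant to
#' within-batch row permutations.
#'
#' @param D_S,D_T n_S x d and n_T x d activation batches (equal d; each
#'   with at least 2 rows).
#' @return scalar loss.
#' @export
coral_loss <- function(D_S, D_T) {
  D_S <- as.matrix(D_S); D_T <- as.matrix(D_T)
  if (ncol(D_S) != ncol(D_T))
    stop("feature dimensionality mismatch between source and target")
  d <- ncol(D_S)
  diffC <- batch_covariance(D_S) - batch_covariance(D_T)
  sum(diffC^2) / (4 * d^2)
}

# Loss plus analytic gradients with respect to both activation batches.
# dL/dD_S = H_S D_S (C_S - C_T) / (d^2 (n_S - 1)), H = I - 11'/n.
coral_loss_grads <- function(D_S, D_T) {
  D_S <- as.matrix(D_S); D_T <- as.matrix(D_T)
  d <- ncol(D_S)
  CS <- batch_covariance(D_S); CT <- batch_covariance(D_T)
  diffC <- CS - CT
  loss <- sum(diffC^2) / (4 * d^2)
  centred <- function(D) sweep(D, 2, colMeans(D))
  dS <- centred(D_S) %*% diffC / (d^2 * (nrow(D_S) - 1))
  dT <- -centred(D_T) %*% diffC / (d^2 * (nrow(D_T) - 1))
  list(loss = loss, dS = dS, dT = dT)
}

#' Joint classification + CORAL loss
#'
#' `l = l_CLASS + lambda * l_CORAL`. With `lambda = 0` adaptation is
#' disabled and the joint loss reduces to the classification loss alone.
#'
#' @param l_class classification loss.
#' @param l_coral CORAL loss.
#' @param lambda nonnegative adaptation weight.
#' @return scalar joint loss.
#' @export
joint_loss <- function(l_class, l_coral, lambda) {
  stopifnot(is.finite(l_class), is.finite(l_coral), lambda >= 0)
  l_class + lambda * l_coral
}

#' CORAL adaptation configuration
#'
#' @param lambda nonnegative weight of the CORAL term, or `"auto"` to tune
#'   over `lambda_grid` by source-validation accuracy.
#' @param adapted_layer which activations feed the CORAL loss; currently
#'   the final dense layer's pre-softmax outputs (`"logits"`), the Deep
#'   CORAL convention.
#' @param lambda_grid candidate values for `"auto"` tuning.
#' @return object of class `coral_config`.
#' @export
coral_config <- function(lambda = 1, adapted_layer = "logits",
                         lambda_grid = c(0.1, 0.5, 1, 5, 10)) {
  if (!identical(lambda, "auto")) stopifnot(lambda >= 0)
  stopifnot(identical(adapted_layer, "logits"))
  structure(list(lambda = lambda, adapted_layer = adapted_layer,
                 lambda_grid = lambda_grid),
            class = "coral_config")
}

#' Two-stream CORAL-adapted training
#'
#' Trains a classifier on labelled source data while aligning the
#' second-order statistics of source and target activations. Each step
#' draws one source batch and one (cycled) target batch, computes the
#' classification loss on the source batch only and the CORAL loss on the
#' adapted layer's activations of both streams, and minimizes
#' `l_CLASS + lambda * l_CORAL`. The two streams share all network
#' parameters by construction. Target labels are never used. With
#' `lambda = 0` the loop reduces exactly to [train_classifier()] (bit-for-
#' bit identical weights under the same seed); batches with fewer than two
#' examples skip the CORAL term, whose covariance would be undefined.
#'
#' @param model a `cyto_model` classifier.
#' @param source labelled source `cyto_dataset` or tensor list.
#' @param target unlabelled target `cyto_dataset` or tensor list (labels,
#'   if present, are ignored).
#' @param config a [coral_config()]; `lambda = "auto"` tunes on
#'   `val` source accuracy.
#' @param training a [training_config()].
#' @param val optional source-domain validation data (model selection and
#'   lambda tuning).
#' @param verbose print progress.
#' @return list with `model`, `history`, `lambda`.
#' @export
adapt_train <- function(model, source, target, config = coral_config(),
                        training = training_config(), val = NULL,
                        verbose = FALSE) {
  tr <- as_tensors(source, model$input_shape)
  vl <- if (is.null(val)) NULL else as_tensors(val, model$input_shape)
  tg <- if (is.null(target)) NULL else as_tensors(target, model$input_shape)
  if (!is.null(tg) && tensor_n(tg) == 0) tg <- NULL
  lambda <- config$lambda
  if (identical(lambda, "auto")) {
    lambda <- tune_lambda(model, tr, tg, config, training, vl,
                          verbose = verbose)
  }
  if (is.null(tg) && lambda > 0) {
    warning("empty target set: falling back to lambda = 0 (no adaptation)")
    lambda <- 0
  }
  fit <- run_training(model, tr, vl, training, target_tens = tg,
                      lambda = lambda, verbose = verbose)
  fit$lambda <- lambda
  fit
}

#' Tune the CORAL weight on source-validation accuracy
#'
#' Trains one model per candidate lambda and keeps the value whose final
#' model has the highest source-domain validation accuracy (training
#' accuracy when no validation data is given), subject to the target-domain
#' features remaining non-degenerate (finite, non-constant logits).
#'
#' @param model,source,target,config,training,val as in [adapt_train()].
#' @param verbose print per-candidate accuracies.
#' @return the selected lambda.
#' @export
tune_lambda <- function(model, source, target, config = coral_config(),
                        training = training_config(), val = NULL,
                        verbose = FALSE) {
  tr <- as_tensors(source, model$input_shape)
  vl <- if (is.null(val)) NULL else as_tensors(val, model$input_shape)
  tg <- if (is.null(target)) NULL else as_tensors(target, model$input_shape)
  best <- list(lambda = 0, acc = -Inf)
  for (lam in config$lambda_grid) {
    fit <- run_training(model, tr, vl, training, target_tens = tg,
                        lambda = lam)
    eval_tens <- vl %||% tr
    acc <- evaluate_classifier(fit$model, eval_tens)$accuracy
    tl <- model_forward(fit$model, tg$x, training = FALSE)
    degenerate <- any(!is.finite(tl)) || stats::sd(as.numeric(tl)) < 1e-10
    if (verbose)
      message(sprintf("lambda %.2g: source acc %.3f%s", lam, acc,
                      if (degenerate) " (degenerate target features)" else ""))
    if (!degenerate && acc > best$acc) best <- list(lambda = lam, acc = acc)
  }
  best$lambda
}
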