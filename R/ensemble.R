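# Majority-vote ensembling of independently trained classifiers.

#' Majority vote over a classifier indicator matrix
#'
#' Each row of `votes` is one classifier's one-hot prediction over the
#' classes (row sums must equal exactly 1); the winner is the class with
#' the maximal column sum. Ties are resolved by the highest summed
#' confidence among the tied classes when per-classifier confidence
#' vectors are supplied, falling back to the lowest class index in
#' severity order — a deterministic, documented rule.
#'
#' @param votes K x N indicator matrix (K classifiers, N classes).
#' @param confidences optional K x N matrix of per-classifier scores used
#'   only for tie-breaking.
#' @return winning class index (integer, 1-based) with name taken from the
#'   columns of `votes` when present.
#' @export
majority_vote <- function(votes, confidences = NULL) {
  votes <- as.matrix(votes)
  if (any(votes != 0 & votes != 1) || any(rowSums(votes) != 1))
    stop("vote error: each classifier row must be a one-hot indicator")
  tally <- colSums(votes)
  top <- which(tally == max(tally))
  win <- if (length(top) == 1) {
    top
  } else if (!is.null(confidences)) {
    conf <- colSums(as.matrix(confidences))[top]
    cand <- top[conf == max(conf)]
    cand[1]                      # equal confidence: lowest class index
  } else {
    top[1]
  }
  out <- as.integer(win)
  if (!is.null(colnames(votes))) names(out) <- colnames(votes)[win]
  out
}

#' Ensemble prediction by majority voting
#'
#' Each model predicts independently (argmax of its 4-class scores); per
#' image the one-hot votes are tallied and [majority_vote()] picks the
#' final class, using the summed softmax confidences for tie-breaking.
#'
#' @param models nonempty list of `cyto_model` classifiers.
#' @param data a `cyto_dataset`, tensor list or input array.
#' @return factor of predicted Bethesda classes.
#' @export
ensemble_predict <- function(models, data) {
  if (length(models) < 1) stop("need at least one model")
  score_list <- lapply(models, function(m) {
    sc <- predict_scores(m, data)
    if (ncol(sc) != 4)
      stop("contract error: model output dimension must be 4")
    sc
  })
  n <- nrow(score_list[[1]])
  out <- integer(n)
  for (i in seq_len(n)) {
    votes <- matrix(0L, length(models), 4)
    conf <- matrix(0, length(models), 4)
    for (k in seq_along(models)) {
      sc <- score_list[[k]][i, ]
      votes[k, which.max(sc)] <- 1L
      conf[k, ] <- as.numeric(softmax(matrix(sc, 1)))
    }
    out[i] <- majority_vote(votes, conf)
  }
  bethesda_factor(out)
}
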