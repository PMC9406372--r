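# Shared fixtures: tiny datasets and stub models, all generated in code.

tiny_counts <- function(n = 8) {
  stats::setNames(rep(n, 4), bethesda_classes())
}

tiny_source <- function(n = 8, seed = 11, resolution = 24) {
  synth_dataset(tiny_counts(n), preparation_style("source"),
                seed = seed, resolution = resolution)
}

tiny_target <- function(n = 6, seed = 22, resolution = 24) {
  synth_dataset(tiny_counts(n), preparation_style("target"),
                seed = seed, resolution = resolution)
}

# classifier stub with fixed output scores, shaped like a cyto_model for
# ensemble tests
stub_scorer <- function(score_fn, input_shape = c(24, 24, 3)) {
  structure(list(stub_fn = score_fn, input_shape = input_shape,
                 spec = list(name = "stub", layers = list()),
                 layers = list()),
            class = c("stub_scorer", "cyto_model"))
}

# route predict_scores through the stub
predict_scores_stub <- function(models, n) {
  lapply(models, function(m) m$stub_fn(n))
}

# naive quadruple-loop valid cross-correlation oracle (single channel pair)
oracle_conv_one <- function(I, K) {
  k <- nrow(K)
  oh <- nrow(I) - k + 1; ow <- ncol(I) - k + 1
  out <- matrix(0, oh, ow)
  for (y in seq_len(oh)) for (x in seq_len(ow)) {
    s <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      s <- s + I[y + a - 1, x + b - 1] * K[a, b]
    }
    out[y, x] <- s
  }
  out
}

# naive Eq.-style multi-channel conv oracle
oracle_conv <- function(inputs, kernels, biases, activation = "linear") {
  N <- length(inputs); M <- length(kernels[[1]])
  lapply(seq_len(M), function(j) {
    acc <- Reduce(`+`, lapply(seq_len(N), function(i)
      oracle_conv_one(inputs[[i]], kernels[[i]][[j]])))
    z <- acc + biases[j]
    switch(activation, relu = pmax(z, 0), linear = z)
  })
}

# textbook two-pass covariance oracle
oracle_cov <- function(D) {
  n <- nrow(D)
  mu <- colMeans(D)
  acc <- matrix(0, ncol(D), ncol(D))
  for (i in seq_len(n)) acc <- acc + tcrossprod(D[i, ] - mu)
  acc / (n - 1)
}

# exhaustive concordant-pair AUC oracle
oracle_auc <- function(pos, score) {
  ip <- which(pos); in_ <- which(!pos)
  tot <- 0
  for (i in ip) for (j in in_) {
    tot <- tot + if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
  }
  tot / (length(ip) * length(in_))
}
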