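test_that("confusion_matrix counts truth-by-prediction", {
  lv <- c("A", "B")
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), levels = lv)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2))
  perfect <- confusion_matrix(bethesda_factor(c(0, 1, 2, 3)),
                              bethesda_factor(c(0, 1, 2, 3)))
  expect_equal(unname(perfect), diag(1L, 4))
  empty <- confusion_matrix(character(0), character(0), levels = lv)
  expect_true(all(empty == 0))
  expect_error(confusion_matrix(c("A"), c("A", "B"), levels = lv),
               "contract error")
})

test_that("classification_report computes the documented metrics", {
  # diagonal matrix: perfect scores
  rep0 <- classification_report(diag(5L, 4))
  expect_equal(rep0$accuracy, 1)
  expect_equal(rep0$fpr, 0)
  expect_equal(rep0$fnr, 0)
  # worked binary example [[8,2],[1,9]]
  cm <- matrix(c(8L, 1L, 2L, 9L), 2,
               dimnames = list(truth = c("neg", "pos"),
                               pred = c("neg", "pos")))
  r <- classification_report(cm)
  expect_equal(r$accuracy, 0.85)
  expect_equal(r$per_class$precision[2], 9 / 11)
  expect_equal(r$per_class$recall[2], 0.9)
  # all-one-class predictions on balanced 4-class data: chance accuracy
  all_one <- matrix(0L, 4, 4); all_one[, 1] <- 10L
  expect_warning(r1 <- classification_report(all_one), "zero denominator")
  expect_equal(r1$accuracy, 0.25)
  # zero-support class yields 0 metrics, not NaN
  zs <- diag(3L, 4); zs[2, ] <- 0L
  expect_warning(rz <- classification_report(zs), "zero denominator")
  expect_false(any(is.nan(unlist(rz$per_class[, -1]))))
})

test_that("accuracy equals weighted recall equals trace/total (property)", {
  set.seed(21)
  for (i in 1:20) {
    cm <- matrix(rpois(16, 5), 4)
    if (sum(cm) == 0) next
    r <- suppressWarnings(classification_report(cm))
    expect_equal(r$accuracy, sum(diag(cm)) / sum(cm))
    expect_equal(r$recall, r$accuracy)
  }
})

test_that("roc_auc matches the concordant-pair oracle and edge cases", {
  # worked example: 3 of 4 pairs concordant
  truth <- c("pos", "pos", "neg", "neg")
  sc <- c(0.9, 0.4, 0.6, 0.1)
  r <- roc_auc(factor(truth, levels = c("neg", "pos")), sc, scheme = "binary")
  expect_equal(r$auc, 0.75)
  # perfect and inverted rankings
  expect_equal(roc_auc(factor(truth, levels = c("neg", "pos")),
                       c(1, 0.9, 0.2, 0.1), scheme = "binary")$auc, 1.0)
  expect_equal(roc_auc(factor(truth, levels = c("neg", "pos")),
                       c(0.1, 0.2, 0.9, 1), scheme = "binary")$auc, 0.0)
  # random small inputs vs the exhaustive pair-count oracle (with ties)
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || !any(pos)) next
    score <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    lab <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    expect_equal(roc_auc(lab, score, scheme = "binary")$auc,
                 oracle_auc(pos, score))
  }
  # multiclass one-vs-rest macro average
  f <- bethesda_factor(rep(bethesda_classes(), each = 3))
  scm <- matrix(stats::runif(48), 12, 4)
  scm[cbind(seq_len(12), as.integer(f))] <-
    scm[cbind(seq_len(12), as.integer(f))] + 2
  m <- roc_auc(f, scm)
  expect_equal(m$auc, mean(m$per_class))
  expect_equal(m$auc, 1.0)  # +2 margin makes the ranking perfect
  expect_error(roc_auc(factor(rep("pos", 3), levels = c("neg", "pos")),
                       c(1, 2, 3), scheme = "binary"), "single-class")
})

test_that("binary grouping equals collapsing the 4x4 block sums", {
  expect_identical(as.character(binarize_labels(c("NILM", "LSIL"))),
                   c("negative", "negative"))
  expect_identical(as.character(binarize_labels(c("HSIL", "SCC"))),
                   c("positive", "positive"))
  expect_length(binarize_labels(character(0)), 0)
  set.seed(41)
  truth <- bethesda_factor(sample(0:3, 60, replace = TRUE))
  pred <- bethesda_factor(sample(0:3, 60, replace = TRUE))
  cm4 <- confusion_matrix(truth, pred)
  cm2 <- confusion_matrix(binarize_labels(truth), binarize_labels(pred),
                          levels = c("negative", "positive"))
  blocks <- rbind(
    c(sum(cm4[1:2, 1:2]), sum(cm4[1:2, 3:4])),
    c(sum(cm4[3:4, 1:2]), sum(cm4[3:4, 3:4])))
  expect_equal(unname(cm2), blocks)
})

test_that("consistency_study summarizes multi-run accuracies", {
  # closed-form sample statistics
  r <- consistency_study(function(s) c(0.99, 0.97)[s], seeds = 1:2)
  expect_equal(r$mean, 0.98)
  expect_equal(r$sd, sqrt(sum((c(0.99, 0.97) - 0.98)^2) / 1))
  expect_equal(r$sd, 0.014142, tolerance = 1e-4)
  # fixed stub values
  vals <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  r5 <- consistency_study(function(s) vals[s], n_runs = 5)
  expect_equal(r5$mean, 0.7)
  expect_equal(r5$max, 0.9)
  expect_equal(r5$min, 0.5)
  # identical deterministic runs: zero spread
  rd <- consistency_study(function(s) 0.8, n_runs = 3)
  expect_equal(rd$sd, 0)
  # failures flagged, not fatal
  rf <- consistency_study(function(s) if (s == 2) stop("boom") else 0.5,
                          n_runs = 3)
  expect_identical(rf$failures, c(FALSE, TRUE, FALSE))
  expect_equal(rf$mean, 0.5)
  expect_error(consistency_study(function(s) 1, seeds = 1), "at least 2")
})

test_that("gradient saliency matches the analytic gradient of a linear scorer", {
  # dense-only model: score = W x, gradient = W row
  spec <- architecture_spec(c(8, 8, 3), list(
    list(type = "flatten"),
    list(type = "dense", units = 4, activation = "linear")))
  m <- build_cnn(spec, seed = 1)
  img <- array(stats::runif(8 * 8 * 3), dim = c(8, 8, 3))
  sal <- gradient_saliency(m, img, class_index = 2)
  w <- array(m$layers[[2]]$W[, 2], dim = c(8, 8, 3))
  want <- pmax(abs(w[, , 1]), abs(w[, , 2]), abs(w[, , 3]))
  want <- (want - min(want)) / (max(want) - min(want))
  expect_equal(sal, want, tolerance = 1e-10)
  expect_true(all(sal >= 0 & sal <= 1))
  expect_equal(dim(sal), c(8L, 8L))
  # constant (all-frozen zero-weight) model: all-zero map after the guard
  mz <- m
  mz$layers[[2]]$W[] <- 0
  expect_true(all(gradient_saliency(mz, img, class_index = 1) == 0))
})

test_that("saliency of a trained CNN concentrates on cells", {
  ds <- synth_dataset(c(NILM = 20, SCC = 20), seed = 91, resolution = 24)
  m <- build_cnn(tiny_cnn_spec(24, c(6, 12), 16), seed = 4)
  fit <- train_classifier(m, ds, config = training_config(
    epochs = 30, learning_rate = 1e-3, seed = 10))
  imgs <- lapply(1:20, function(s)
    synth_cell_image(if (s %% 2) "NILM" else "SCC", seed = 300 + s,
                     resolution = 24))
  inside <- numeric(0); outside <- numeric(0)
  for (im in imgs) {
    sal <- gradient_saliency(fit$model, im)
    mask <- attr(im, "cell_mask")
    inside <- c(inside, mean(sal[mask]))
    outside <- c(outside, mean(sal[!mask]))
  }
  expect_gt(mean(inside), mean(outside))
})
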