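test_that("batch_covariance matches the worked example and the oracle", {
  D <- matrix(c(1, 3, 5, 2, 4, 6), 3)   # rows (1,2),(3,4),(5,6)
  expect_equal(batch_covariance(D), matrix(4, 2, 2))
  # constant rows give the zero matrix
  expect_equal(batch_covariance(matrix(1, 4, 3)), matrix(0, 3, 3))
  # random batches vs the two-pass mean/outer-product oracle
  set.seed(3)
  for (i in 1:5) {
    D <- matrix(stats::rnorm(15), 5, 3)
    C <- batch_covariance(D)
    expect_equal(C, oracle_cov(D), tolerance = 1e-10)
    expect_equal(C, t(C))
    expect_true(min(eigen(C, symmetric = TRUE)$values) > -1e-10)
  }
  expect_error(batch_covariance(matrix(1, 1, 3)), "degenerate batch")
})

test_that("coral_loss satisfies its closed form and symmetries", {
  D <- matrix(stats::rnorm(20), 5, 4)
  expect_equal(coral_loss(D, D), 0)
  # worked 2x2 example: C_S = [[2,2],[2,2]], C_T = 0 -> 16/(4*4) = 1
  DS <- matrix(c(0, 2, 0, 2), 2)
  DT <- matrix(0, 2, 2)
  expect_equal(coral_loss(DS, DT), 1.0)
  # symmetry and row-permutation invariance
  set.seed(5)
  A <- matrix(stats::rnorm(24), 6, 4); B <- matrix(stats::rnorm(24), 6, 4)
  expect_equal(coral_loss(A, B), coral_loss(B, A))
  expect_equal(coral_loss(A[sample(6), ], B), coral_loss(A, B))
  # scaling features by s scales the loss by s^4
  s <- 1.7
  expect_equal(coral_loss(s * A, s * B), s^4 * coral_loss(A, B),
               tolerance = 1e-10)
  expect_error(coral_loss(A, B[, 1:3]), "dimensionality mismatch")
})

test_that("coral gradients match central finite differences", {
  set.seed(11)
  for (case in 1:3) {
    DS <- matrix(stats::rnorm(12), 4, 3)
    DT <- matrix(stats::rnorm(9), 3, 3)   # unequal batch sizes allowed
    g <- cytocoral:::coral_loss_grads(DS, DT)
    eps <- 1e-6
    num_g <- function(M, other, src) {
      out <- M * 0
      for (i in seq_along(M)) {
        a <- M; a[i] <- a[i] + eps
        b <- M; b[i] <- b[i] - eps
        out[i] <- if (src) (coral_loss(a, other) - coral_loss(b, other)) / (2 * eps)
        else (coral_loss(other, a) - coral_loss(other, b)) / (2 * eps)
      }
      out
    }
    expect_equal(g$dS, num_g(DS, DT, TRUE), tolerance = 1e-4)
    expect_equal(g$dT, num_g(DT, DS, FALSE), tolerance = 1e-4)
    expect_equal(g$loss, coral_loss(DS, DT))
  }
})

test_that("joint_loss combines the terms linearly", {
  expect_equal(joint_loss(0.7, 0.2, 0), 0.7)
  expect_equal(joint_loss(0.7, 0.2, 1.5), 1.0)
  expect_equal(joint_loss(0, 0, 10), 0)
  expect_error(joint_loss(0.5, 0.1, -1))
})

test_that("lambda = 0 adaptation reduces exactly to plain training", {
  src <- synth_dataset(c(NILM = 10, SCC = 10), seed = 41, resolution = 16)
  tgt <- synth_dataset(c(NILM = 6, SCC = 6), preparation_style("target"),
                       seed = 42, resolution = 16)
  m <- build_cnn(tiny_cnn_spec(16, c(4), 8), seed = 1)
  cfg <- training_config(epochs = 2, seed = 6)
  plain <- train_classifier(m, src, config = cfg)
  adapted <- adapt_train(m, src, tgt, coral_config(lambda = 0), cfg)
  expect_identical(cytocoral:::get_weights(plain$model),
                   cytocoral:::get_weights(adapted$model))
  expect_equal(adapted$lambda, 0)
  # empty target falls back to lambda = 0 with a warning
  empty <- synth_dataset(c(NILM = 0), seed = 1, resolution = 16)
  expect_warning(
    fb <- adapt_train(m, src, empty, coral_config(lambda = 1), cfg),
    "empty target")
  expect_identical(cytocoral:::get_weights(fb$model),
                   cytocoral:::get_weights(plain$model))
})

test_that("the coral term logged during training equals an offline recompute", {
  src <- synth_dataset(c(NILM = 8, SCC = 8), seed = 51, resolution = 16)
  tgt <- synth_dataset(c(NILM = 8, SCC = 8), preparation_style("target"),
                       seed = 52, resolution = 16)
  m <- build_cnn(tiny_cnn_spec(16, c(4), 8), seed = 2)
  # single full-batch step: the logged epoch CORAL loss is the loss of the
  # initial model's activations, recomputable offline
  cfg <- training_config(epochs = 1, batch_size = 16, seed = 3)
  fit <- adapt_train(m, src, tgt, coral_config(lambda = 1), cfg)
  tr <- cytocoral:::as_tensors(src, m$input_shape)
  tg <- cytocoral:::as_tensors(tgt, m$input_shape)
  with_seed_order <- function() {
    # reproduce the loop's batch orders under the same seed
    set.seed(3)
    perm <- sample.int(16)
    t_perm <- sample.int(16)
    list(perm, t_perm)
  }
  ords <- with_seed_order()
  ls <- cytocoral:::model_forward(m, cytocoral:::tensor_batch(tr, ords[[1]]))
  lt <- cytocoral:::model_forward(m, cytocoral:::tensor_batch(tg, ords[[2]]))
  expect_equal(fit$history$coral_loss[1], coral_loss(ls, lt),
               tolerance = 1e-12)
})

test_that("cross-domain raw-pixel CORAL distance exceeds within-domain", {
  n <- 40
  srcA <- synth_dataset(tiny_counts(n %/% 4), seed = 61, resolution = 24)
  srcB <- synth_dataset(tiny_counts(n %/% 4), seed = 62, resolution = 24)
  tgt <- synth_dataset(tiny_counts(n %/% 4), preparation_style("target"),
                       seed = 63, resolution = 24)
  fa <- pixel_features(srcA); fb <- pixel_features(srcB)
  ft <- pixel_features(tgt)
  cross <- coral_loss(fa, ft)
  within <- coral_loss(fa, fb)
  expect_gt(cross, within)
})
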