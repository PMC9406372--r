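test_that("relu matches its definition on the documented cases", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(3), 3)
  expect_equal(relu(0), 0)
  x <- matrix(c(-2, 0.5, 0, 7), 2)
  expect_equal(relu(x), matrix(c(0, 0.5, 0, 7), 2))
})

test_that("conv_forward matches the naive quadruple-loop oracle", {
  # worked single-channel example: valid cross-correlation + bias + relu
  out <- conv_forward(matrix(c(1, 3, 2, 4), 2), matrix(c(1, 0, 0, 1), 2),
                      biases = 1, activation = "relu")
  expect_equal(out, matrix(6, 1, 1))
  # identity 1x1 kernel
  I <- matrix(stats::runif(25), 5)
  expect_equal(conv_forward(I, matrix(1, 1, 1)), I)
  # saturating negative bias under relu
  expect_true(all(conv_forward(I, matrix(1, 3, 3), biases = -100,
                               activation = "relu") == 0))
  # random multi-channel cases against the loop oracle
  set.seed(42)
  for (case in 1:5) {
    N <- sample(1:3, 1); M <- sample(1:3, 1); k <- sample(2:3, 1)
    inputs <- lapply(seq_len(N), function(i) matrix(stats::rnorm(64), 8))
    kernels <- lapply(seq_len(N), function(i)
      lapply(seq_len(M), function(j) matrix(stats::rnorm(k * k), k)))
    biases <- stats::rnorm(M)
    got <- conv_forward(inputs, kernels, biases, "relu")
    want <- oracle_conv(inputs, kernels, biases, "relu")
    if (M == 1) got <- list(got)
    for (j in seq_len(M)) expect_equal(got[[j]], want[[j]], tolerance = 1e-6)
  }
  expect_error(conv_forward(list(I, I), list(list(matrix(1, 2, 2)))),
               "dimension error")
})

test_that("maxpool2x2 takes disjoint block maxima and halves dims", {
  expect_equal(maxpool2x2(matrix(1:4, 2)), matrix(4, 1, 1))
  cst <- matrix(7, 4, 4)
  expect_true(all(maxpool2x2(cst) == 7))
  set.seed(1)
  m <- matrix(sample(1:16), 4)
  got <- maxpool2x2(m)
  expect_equal(dim(got), c(2L, 2L))
  for (i in 1:2) for (j in 1:2) {
    expect_equal(got[i, j], max(m[2 * i - 1:0, 2 * j - 1:0]))
  }
  # odd dims: floor division drops trailing row/col
  expect_equal(dim(maxpool2x2(matrix(1:25, 5))), c(2L, 2L))
})

test_that("reference architectures hit the published budgets exactly", {
  expect_identical(count_trainable_params(cnn_reference_spec()), 60772L)
  ae <- ae_reference_spec()
  expect_identical(count_trainable_params(ae$encoder) +
                     count_trainable_params(ae$decoder), 20355L)
  expect_identical(count_trainable_params(ae_cnn_classifier_spec()), 10292L)
  # built models agree with the closed-form spec totals
  expect_identical(count_trainable_params(build_cnn(cnn_reference_spec())),
                   60772L)
  built_ae <- build_autoencoder(ae$encoder, ae$decoder)
  expect_identical(count_trainable_params(built_ae), 20355L)
  expect_identical(count_trainable_params(build_cnn(ae_cnn_classifier_spec())),
                   10292L)
})

test_that("parameter counting follows the closed forms", {
  dense_only <- architecture_spec(64, list(
    list(type = "dense", units = 4)))
  expect_identical(count_trainable_params(dense_only), 260L)  # (64+1)*4
  d84 <- architecture_spec(8, list(list(type = "dense", units = 4)))
  expect_identical(count_trainable_params(d84), 36L)          # (8+1)*4
  conv38 <- architecture_spec(c(8, 8, 3), list(
    list(type = "conv", filters = 8, kernel = 3)))
  expect_identical(count_trainable_params(conv38), 224L)      # 27*8+8
  # frozen layers are excluded from model counts
  m <- build_cnn(tiny_cnn_spec(16, c(4), 8))
  for (i in seq_along(m$layers)) m$layers[[i]]$trainable <- FALSE
  expect_identical(count_trainable_params(m), 0L)
})

test_that("the budget solver recovers the pinned CNN widths", {
  sols <- solve_cnn_widths(60772, resolution = 64, n_blocks = 4,
                           width_grid = c(40, 48), max_solutions = 5)
  expect_true(any(vapply(sols, function(w)
    identical(w, c(40, 48, 40, 40)), logical(1))))
})

test_that("built CNN forward pass satisfies the score contract", {
  m <- build_cnn(tiny_cnn_spec(16, c(4, 8), 8), seed = 1)
  x <- array(stats::runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  sc <- predict_scores(m, x)
  expect_equal(dim(sc), c(2L, 4L))
  expect_true(all(is.finite(sc)))
  expect_error(build_cnn(architecture_spec(c(16, 16, 3), list(
    list(type = "conv", filters = 4)))), "must end with a dense layer")
  expect_error(architecture_spec(c(16, 16, 3), list(
    list(type = "dense", units = 4))), "flattened")
})

test_that("autoencoder round-trip preserves shape and validates mirroring", {
  sp <- tiny_ae_spec(16, c(4, 6))
  ae <- build_autoencoder(sp$encoder, sp$decoder, seed = 2)
  x <- array(0, dim = c(16, 16, 3, 1))
  z <- cytocoral:::model_forward(ae$encoder, x)
  y <- cytocoral:::model_forward(ae$decoder, z)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_lt(prod(dim(z)[1:3]), prod(dim(x)[1:3]))  # compressing bottleneck
  bad_dec <- architecture_spec(c(4, 4, 6), list(
    list(type = "upsample"),
    list(type = "conv", filters = 3, activation = "sigmoid")))
  expect_error(build_autoencoder(sp$encoder, bad_dec), "reverse the encoder")
})

test_that("training is deterministic, seeded and monotone on an easy task", {
  ds <- synth_dataset(c(NILM = 20, SCC = 20), seed = 31, resolution = 24)
  m <- build_cnn(tiny_cnn_spec(24, c(4, 8), 16), seed = 5)
  cfg <- training_config(epochs = 2, learning_rate = 1e-3, seed = 7)
  f1 <- train_classifier(m, ds, config = cfg)
  f2 <- train_classifier(m, ds, config = cfg)
  expect_identical(cytocoral:::get_weights(f1$model),
                   cytocoral:::get_weights(f2$model))
  expect_equal(nrow(f1$history), 2)
  # zero epochs: initial weights, empty history
  f0 <- train_classifier(m, ds, config = training_config(epochs = 0))
  expect_identical(cytocoral:::get_weights(f0$model),
                   cytocoral:::get_weights(m))
  expect_equal(nrow(f0$history), 0)
  expect_error(train_classifier(m, synth_dataset(c(NILM = 0), seed = 1,
                                                 resolution = 24)),
               "empty training set")
})

test_that("a tiny CNN learns two well-separated classes", {
  ds <- synth_dataset(c(NILM = 40, SCC = 40), seed = 77, resolution = 24)
  m <- build_cnn(tiny_cnn_spec(24, c(6, 12), 16), seed = 3)
  fit <- train_classifier(m, ds, config = training_config(
    epochs = 25, learning_rate = 1e-3, batch_size = 16, seed = 9))
  expect_gte(max(fit$history$train_acc), 0.9)
})

test_that("AE reconstruction error decreases across early epochs", {
  ds <- synth_dataset(c(NILM = 10, SCC = 10), seed = 13, resolution = 16)
  improved <- vapply(1:5, function(s) {
    sp <- tiny_ae_spec(16, c(4, 6))
    ae <- build_autoencoder(sp$encoder, sp$decoder, seed = s)
    h <- train_autoencoder(ae, ds, config = training_config(
      "ae", epochs = 10, learning_rate = 1e-3, seed = s))$history
    h$train_loss[10] < h$train_loss[1]
  }, logical(1))
  expect_gte(sum(improved), 4)
})

test_that("transfer head adapter swaps and freezes correctly", {
  bb <- stub_backbone(feature_dim = 8, resolution = 16, seed = 1)
  full_params <- count_trainable_params(bb)
  head <- adapt_transfer_head(bb, mode = "head_only", seed = 2)
  expect_identical(count_trainable_params(head), 36L)     # (8+1)*4
  full <- adapt_transfer_head(bb, mode = "full", seed = 2)
  backbone_only <- full_params - 36L
  expect_identical(count_trainable_params(full), backbone_only + 36L)
  x <- array(stats::runif(16 * 16 * 3), dim = c(16, 16, 3, 1))
  expect_length(predict_scores(head, x), 4)
  # frozen layers stay frozen through training
  ds <- synth_dataset(c(NILM = 6, SCC = 6), seed = 2, resolution = 16)
  w0 <- cytocoral:::get_weights(head)
  fit <- train_classifier(head, ds, config = training_config(epochs = 1))
  w1 <- cytocoral:::get_weights(fit$model)
  frozen <- seq_len(length(w1) - 1)
  expect_identical(w1[frozen], w0[frozen])
  expect_false(identical(w1[[length(w1)]], w0[[length(w0)]]))
  no_dense <- build_model_no_dense <- structure(
    list(spec = list(layers = list()), layers = list(),
         input_shape = c(16, 16, 3)), class = "cyto_model")
  expect_error(adapt_transfer_head(no_dense), "adapter error")
})

test_that("network outputs stay finite on [0,1] inputs", {
  m <- build_cnn(tiny_cnn_spec(16, c(4, 8), 8), seed = 11)
  for (fill in c(0, 0.5, 1)) {
    x <- array(fill, dim = c(16, 16, 3, 1))
    expect_true(all(is.finite(predict_scores(m, x))))
  }
})
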