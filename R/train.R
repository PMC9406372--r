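# Forward/backward orchestration and training loops.

model_forward <- function(model, x, training = FALSE, want_cache = FALSE) {
  caches <- if (want_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      r <- conv_layer_forward(x, ly$W, ly$b, ly$kernel, ly$padding,
                              ly$activation, want_cache)
      if (want_cache) { caches[[i]] <- r; x <- r$out } else x <- r
    } else if (ly$type == "maxpool") {
      r <- maxpool_forward(x)
      if (want_cache) caches[[i]] <- r
      x <- r$out
    } else if (ly$type == "upsample") {
      r <- upsample_forward(x)
      if (want_cache) caches[[i]] <- r
      x <- r$out
    } else if (ly$type == "flatten") {
      r <- flatten_forward(x)
      if (want_cache) caches[[i]] <- r
      x <- r$out
    } else if (ly$type == "dense") {
      r <- dense_forward(x, ly$W, ly$b, ly$activation, want_cache)
      if (want_cache) { caches[[i]] <- r; x <- r$out } else x <- r
    } else if (ly$type == "dropout") {
      r <- dropout_forward(x, ly$rate, training)
      if (want_cache) caches[[i]] <- r
      x <- r$out
    }
  }
  if (want_cache) list(out = x, caches = caches) else x
}

# Backpropagate dout through the model; returns per-layer weight gradients
# and the gradient with respect to the input.
model_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      in_dim <- caches[[i]]$padded_dim
      if (ly$padding == "same") {
        p <- (ly$kernel - 1L) %/% 2L
        in_dim[1:2] <- in_dim[1:2] - 2L * p
      }
      r <- conv_layer_backward(dout, caches[[i]], ly$W, ly$kernel,
                               ly$padding, ly$activation, in_dim)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dout <- r$dx
    } else if (ly$type == "maxpool") {
      dout <- maxpool_backward(dout, caches[[i]])
    } else if (ly$type == "upsample") {
      dout <- upsample_backward(dout, caches[[i]])
    } else if (ly$type == "flatten") {
      dout <- flatten_backward(dout, caches[[i]])
    } else if (ly$type == "dense") {
      r <- dense_backward(dout, caches[[i]], ly$W, ly$activation)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dout <- r$dx
    } else if (ly$type == "dropout") {
      dout <- dropout_backward(dout, caches[[i]])
    }
  }
  list(grads = grads, dx = dout)
}

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

adam_step <- function(model, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g) || !isTRUE(model$layers[[i]]$trainable)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mhW <- s$mW / (1 - beta1^t); vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t); vhb <- s$vb / (1 - beta2^t)
    model$layers[[i]]$W <- model$layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

get_weights <- function(model) {
  lapply(model$layers, function(ly)
    if (is.null(ly$W)) NULL else list(W = ly$W, b = ly$b))
}

set_weights <- function(model, w) {
  for (i in seq_along(w)) {
    if (!is.null(w[[i]])) {
      model$layers[[i]]$W <- w[[i]]$W
      model$layers[[i]]$b <- w[[i]]$b
    }
  }
  model
}

#' Training configuration
#'
#' Presets mirror the published protocols: `transfer` = 25 epochs, learning
#' rate 0.001, batch size 16, Adam; `cnn` = 230 epochs at 0.0005; `ae` =
#' 100 epochs at 0.00005; `ae_cnn` = 350 epochs at 0.00005. All presets use
#' Adam and (for classifiers) categorical cross-entropy.
#'
#' @param preset one of `"custom"`, `"transfer"`, `"cnn"`, `"ae"`,
#'   `"ae_cnn"`.
#' @param epochs,learning_rate,batch_size,seed overrides.
#' @return object of class `training_config`.
#' @export
training_config <- function(preset = c("custom", "transfer", "cnn", "ae",
                                       "ae_cnn"),
                            epochs = NULL, learning_rate = NULL,
                            batch_size = NULL, seed = 0L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    custom = list(epochs = 10, learning_rate = 1e-3, batch_size = 16),
    transfer = list(epochs = 25, learning_rate = 1e-3, batch_size = 16),
    cnn = list(epochs = 230, learning_rate = 5e-4, batch_size = 16),
    ae = list(epochs = 100, learning_rate = 5e-5, batch_size = 16),
    ae_cnn = list(epochs = 350, learning_rate = 5e-5, batch_size = 16))
  structure(list(
    preset = preset,
    epochs = as.integer(epochs %||% def$epochs),
    learning_rate = learning_rate %||% def$learning_rate,
    batch_size = as.integer(batch_size %||% def$batch_size),
    optimizer = "adam",
    loss = if (preset == "ae") "mse" else "categorical_crossentropy",
    seed = as.integer(seed)
  ), class = "training_config")
}

# Convert a cyto_dataset (or pass through a tensor list) to model inputs.
as_tensors <- function(data, input_shape) {
  if (is.list(data) && !inherits(data, "cyto_dataset") &&
      !is.null(data$x)) {
    return(data)
  }
  n <- n_images(data)
  if (length(input_shape) != 3)
    stop("model expects flattened input; encode the dataset first")
  x <- array(0, dim = c(input_shape[1], input_shape[2], 3, n))
  for (i in seq_len(n)) {
    x[, , , i] <- resize_image(unclass_image(data$images[[i]]),
                               input_shape[1], input_shape[2])
  }
  y <- if (nrow(data$meta) > 0) bethesda_factor(data$meta$label) else NULL
  list(x = x, y = y, meta = data$meta)
}

tensor_n <- function(tens) {
  d <- dim(tens$x)
  if (length(d) == 2) d[1] else d[length(d)]
}

tensor_batch <- function(tens, idx) {
  d <- dim(tens$x)
  if (length(d) == 2) tens$x[idx, , drop = FALSE]
  else tens$x[, , , idx, drop = FALSE]
}

cross_entropy_grad <- function(logits, y_int) {
  n <- nrow(logits)
  p <- softmax(logits)
  Y <- matrix(0, n, ncol(logits))
  Y[cbind(seq_len(n), y_int)] <- 1
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y_int)], 1e-12)))
  list(loss = loss, dlogits = (p - Y) / n, pred = max.col(p, "first"))
}

#' Class scores for a batch of images
#'
#' @param model a trained classifier.
#' @param data a `cyto_dataset`, tensor list or raw input array.
#' @return n x 4 score (logit) matrix.
#' @export
predict_scores <- function(model, data) {
  x <- if (is.array(data)) {
    if (length(dim(data)) == 3) array(as.numeric(data), c(dim(data), 1))
    else data
  } else {
    as_tensors(data, model$input_shape)$x
  }
  model_forward(model, x, training = FALSE)
}

#' Predicted Bethesda classes
#'
#' The prediction is the index of the highest value of the final dense
#' layer's length-4 output.
#'
#' @inheritParams predict_scores
#' @return factor of predicted classes.
#' @export
predict_classes <- function(model, data) {
  sc <- predict_scores(model, data)
  bethesda_factor(max.col(sc, "first"))
}

evaluate_classifier <- function(model, tens) {
  logits <- model_forward(model, tens$x, training = FALSE)
  ce <- cross_entropy_grad(logits, as.integer(tens$y))
  list(loss = ce$loss, accuracy = mean(ce$pred == as.integer(tens$y)))
}

# Shared mini-batch loop for plain and CORAL-adapted training. With
# lambda = 0 (or no target) the target stream is skipped entirely, so plain
# training is the exact lambda = 0 reduction of the adapted loop.
run_training <- function(model, train_tens, val_tens, config,
                         target_tens = NULL, lambda = 0, verbose = FALSE) {
  n <- tensor_n(train_tens)
  if (n == 0) stop("empty training set")
  y_int <- as.integer(train_tens$y)
  use_coral <- !is.null(target_tens) && lambda > 0
  nt <- if (use_coral) tensor_n(target_tens) else 0L
  hist <- list()
  best <- list(metric = -Inf, weights = get_weights(model))
  state <- adam_init(model)
  t_step <- 0L
  with_seed(config$seed, {
    if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      t_perm <- if (use_coral) sample.int(nt) else integer(0)
      t_pos <- 0L
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_loss <- 0; ep_correct <- 0; ep_coral <- 0; ncoral <- 0L
      for (bi in batches) {
        xb <- tensor_batch(train_tens, bi)
        fw <- model_forward(model, xb, training = TRUE, want_cache = TRUE)
        ce <- cross_entropy_grad(fw$out, y_int[bi])
        dlogits <- ce$dlogits
        grads_t <- NULL
        if (use_coral) {
          # cycle the shuffled target stream to pair with this source batch
          tb <- integer(0)
          while (length(tb) < length(bi)) {
            take <- min(length(bi) - length(tb), nt - t_pos)
            if (take <= 0) { t_perm <- sample.int(nt); t_pos <- 0L; next }
            tb <- c(tb, t_perm[t_pos + seq_len(take)])
            t_pos <- t_pos + take
          }
          if (length(bi) >= 2 && length(tb) >= 2) {
            xt <- tensor_batch(target_tens, tb)
            fwt <- model_forward(model, xt, training = TRUE, want_cache = TRUE)
            cg <- coral_loss_grads(fw$out, fwt$out)
            ep_coral <- ep_coral + cg$loss; ncoral <- ncoral + 1L
            dlogits <- dlogits + lambda * cg$dS
            grads_t <- model_backward(model, fwt$caches,
                                      lambda * cg$dT)$grads
          }
        }
        bk <- model_backward(model, fw$caches, dlogits)
        grads <- bk$grads
        if (!is.null(grads_t)) {
          for (i in seq_along(grads)) {
            if (!is.null(grads[[i]]) && !is.null(grads_t[[i]])) {
              grads[[i]]$dW <- grads[[i]]$dW + grads_t[[i]]$dW
              grads[[i]]$db <- grads[[i]]$db + grads_t[[i]]$db
            }
          }
        }
        t_step <- t_step + 1L
        up <- adam_step(model, grads, state, config$learning_rate, t_step)
        model <- up$model; state <- up$state
        ep_loss <- ep_loss + ce$loss * length(bi)
        ep_correct <- ep_correct + sum(ce$pred == y_int[bi])
      }
      row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                        train_acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_,
                        coral_loss = if (ncoral > 0) ep_coral / ncoral else NA_real_)
      metric <- row$train_acc
      if (!is.null(val_tens)) {
        ev <- evaluate_classifier(model, val_tens)
        row$val_loss <- ev$loss; row$val_acc <- ev$accuracy
        metric <- ev$accuracy
      }
      if (metric > best$metric) {
        best$metric <- metric
        best$weights <- get_weights(model)
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %d: loss %.4f acc %.3f val %.3f", ep,
                        row$train_loss, row$train_acc, row$val_acc))
    }
  })
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(0), train_loss = numeric(0),
               train_acc = numeric(0), val_loss = numeric(0),
               val_acc = numeric(0), coral_loss = numeric(0))
  final <- model
  model <- if (config$epochs > 0) set_weights(model, best$weights) else model
  list(model = model, final_model = final, history = history)
}

#' Train a classifier
#'
#' Mini-batch Adam training with categorical cross-entropy. Returns the
#' weights from the epoch with the best validation accuracy (training
#' accuracy when no validation split is supplied) plus the per-epoch
#' history. Deterministic for a fixed `config$seed` under single-threaded
#' execution; with `epochs = 0` the initial weights are returned with an
#' empty history.
#'
#' @param model a `cyto_model` classifier.
#' @param train,val `cyto_dataset`s or tensor lists (`val` optional).
#' @param config a [training_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best weights), `final_model`, `history`.
#' @export
train_classifier <- function(model, train, val = NULL,
                             config = training_config(), verbose = FALSE) {
  tr <- as_tensors(train, model$input_shape)
  if (tensor_n(tr) == 0) stop("empty training set")
  vl <- if (is.null(val)) NULL else as_tensors(val, model$input_shape)
  if (!is.null(vl) && tensor_n(vl) == 0) vl <- NULL
  run_training(model, tr, vl, config, verbose = verbose)
}

#' Train an autoencoder
#'
#' Minimizes mean squared reconstruction error of
#' `decoder(encoder(x))` against `x` with Adam. The epoch history records
#' the running training loss (and validation loss when supplied); the
#' returned autoencoder carries the final weights.
#'
#' @param ae a `cyto_autoencoder`.
#' @param train,val `cyto_dataset`s or tensor lists.
#' @param config a [training_config()] (preset `"ae"` recommended).
#' @param verbose print per-epoch progress.
#' @return list with `ae`, `history`.
#' @export
train_autoencoder <- function(ae, train, val = NULL,
                              config = training_config("ae"),
                              verbose = FALSE) {
  tr <- as_tensors(train, ae$encoder$input_shape)
  vl <- if (is.null(val)) NULL else as_tensors(val, ae$encoder$input_shape)
  n <- tensor_n(tr)
  if (n == 0) stop("empty training set")
  hist <- list()
  enc <- ae$encoder; dec <- ae$decoder
  st_e <- adam_init(enc); st_d <- adam_init(dec)
  t_step <- 0L
  with_seed(config$seed, {
    if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        xb <- tensor_batch(tr, bi)
        fe <- model_forward(enc, xb, training = TRUE, want_cache = TRUE)
        fd <- model_forward(dec, fe$out, training = TRUE, want_cache = TRUE)
        err <- fd$out - xb
        loss <- mean(err^2)
        dout <- 2 * err / length(err)
        bd <- model_backward(dec, fd$caches, dout)
        be <- model_backward(enc, fe$caches, bd$dx)
        t_step <- t_step + 1L
        ud <- adam_step(dec, bd$grads, st_d, config$learning_rate, t_step)
        dec <- ud$model; st_d <- ud$state
        ue <- adam_step(enc, be$grads, st_e, config$learning_rate, t_step)
        enc <- ue$model; st_e <- ue$state
        ep_loss <- ep_loss + loss * length(bi)
      }
      row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                        val_loss = NA_real_)
      if (!is.null(vl)) {
        rec <- model_forward(dec, model_forward(enc, vl$x), training = FALSE)
        row$val_loss <- mean((rec - vl$x)^2)
      }
      hist[[ep]] <- row
      if (verbose) message(sprintf("epoch %d: mse %.6f", ep, row$train_loss))
    }
  })
  ae$encoder <- enc; ae$decoder <- dec
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(0), train_loss = numeric(0),
               val_loss = numeric(0))
  list(ae = ae, history = history)
}

#' Encode a dataset through a trained encoder
#'
#' Produces the compressed bottleneck representation of every image; the
#' result is a tensor list directly usable as training data for a
#' downstream classifier.
#'
#' @param encoder the encoder `cyto_model` of an autoencoder.
#' @param dataset a `cyto_dataset` or tensor list.
#' @return tensor list with encoded `x`, original `y` and `meta`.
#' @export
encode_dataset <- function(encoder, dataset) {
  tens <- as_tensors(dataset, encoder$input_shape)
  list(x = model_forward(encoder, tens$x, training = FALSE),
       y = tens$y, meta = tens$meta)
}

#' Save / load a model
#'
#' Weights and spec are serialized with `saveRDS`.
#'
#' @param model a `cyto_model` or `cyto_autoencoder`.
#' @param path file path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
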