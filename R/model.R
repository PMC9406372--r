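# Architecture specifications and model construction.

#' Architecture specification
#'
#' An ordered description of a feed-forward network over
#' conv / maxpool / upsample / flatten / dense / dropout layers, with an
#' input shape. The trainable-parameter total has a closed form:
#' `k^2 * c_in * c_out + c_out` per conv layer and
#' `(d_in + 1) * d_out` per dense layer.
#'
#' @param input_shape integer triple (height, width, channels) or a single
#'   feature dimensionality for dense-only specs.
#' @param layers list of layer descriptions, e.g.
#'   `list(type = "conv", filters = 40, kernel = 3, padding = "valid",
#'   activation = "relu")`, `list(type = "maxpool")`,
#'   `list(type = "upsample")`, `list(type = "flatten")`,
#'   `list(type = "dense", units = 64, activation = "relu")`,
#'   `list(type = "dropout", rate = 0.2)`.
#' @param name optional spec name.
#' @return object of class `architecture_spec` with per-layer inferred
#'   shapes.
#' @export
architecture_spec <- function(input_shape, layers, name = "spec") {
  shape <- as.integer(input_shape)
  spatial <- length(shape) == 3L
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    ly$padding <- ly$padding %||% "same"
    ly$activation <- ly$activation %||% "linear"
    ly$kernel <- as.integer(ly$kernel %||% 3L)
    ly$input_shape <- shape
    switch(ly$type,
      conv = {
        if (!spatial) stop("spec error: conv after flatten")
        oh <- if (ly$padding == "valid") shape[1] - ly$kernel + 1L else shape[1]
        ow <- if (ly$padding == "valid") shape[2] - ly$kernel + 1L else shape[2]
        if (oh < 1 || ow < 1) stop("spec error: spatial dims exhausted")
        shape <- c(oh, ow, as.integer(ly$filters))
      },
      maxpool = {
        if (!spatial) stop("spec error: maxpool after flatten")
        shape <- c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
        if (any(shape[1:2] < 1)) stop("spec error: spatial dims exhausted")
      },
      upsample = {
        if (!spatial) stop("spec error: upsample after flatten")
        shape <- c(shape[1] * 2L, shape[2] * 2L, shape[3])
      },
      flatten = {
        if (!spatial) stop("spec error: flatten twice")
        shape <- prod(shape)
        spatial <- FALSE
      },
      dense = {
        if (spatial) stop("spec error: dense requires flattened input")
        shape <- as.integer(ly$units)
      },
      dropout = {
        stopifnot(ly$rate >= 0, ly$rate < 1)
      },
      stop("spec error: unknown layer type ", ly$type)
    )
    ly$output_shape <- shape
    layers[[i]] <- ly
  }
  structure(list(input_shape = as.integer(input_shape), layers = layers,
                 output_shape = shape, name = name),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec '%s'> input %s, %d layers, %s parameters\n",
              x$name, paste(x$input_shape, collapse = "x"),
              length(x$layers),
              format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}

spec_layer_params <- function(ly) {
  switch(ly$type,
    conv = ly$kernel^2 * ly$input_shape[3] * ly$filters + ly$filters,
    dense = (ly$input_shape + 1) * ly$units,
    0)
}

#' Count trainable parameters
#'
#' Closed-form per-layer counts: `k^2 * c_in * c_out + c_out` for a conv
#' layer, `(d_in + 1) * d_out` for a dense layer, zero for pooling,
#' upsampling, flatten and dropout. For built models, frozen layers are
#' excluded and the count is taken from the actual weight arrays.
#'
#' @param model an `architecture_spec`, `cyto_model` or `cyto_autoencoder`.
#' @return integer parameter total.
#' @export
count_trainable_params <- function(model) {
  if (inherits(model, "architecture_spec")) {
    return(as.integer(sum(vapply(model$layers, spec_layer_params, numeric(1)))))
  }
  if (inherits(model, "cyto_autoencoder")) {
    return(count_trainable_params(model$encoder) +
             count_trainable_params(model$decoder))
  }
  if (inherits(model, "cyto_model")) {
    tot <- 0
    for (ly in model$layers) {
      if (!is.null(ly$W) && isTRUE(ly$trainable))
        tot <- tot + length(ly$W) + length(ly$b)
    }
    return(as.integer(tot))
  }
  stop("unsupported model object")
}

init_layer <- function(ly) {
  out <- ly
  out$trainable <- TRUE
  if (ly$type == "conv") {
    fan_in <- ly$kernel^2 * ly$input_shape[3]
    out$W <- matrix(stats::rnorm(fan_in * ly$filters, 0, sqrt(2 / fan_in)),
                    fan_in, ly$filters)
    out$b <- numeric(ly$filters)
  } else if (ly$type == "dense") {
    fan_in <- ly$input_shape
    out$W <- matrix(stats::rnorm(fan_in * ly$units, 0, sqrt(2 / fan_in)),
                    fan_in, ly$units)
    out$b <- numeric(ly$units)
  }
  out
}

build_model <- function(spec, seed = 0L) {
  layers <- with_seed(seed, lapply(spec$layers, init_layer))
  structure(list(spec = spec, layers = layers,
                 input_shape = spec$input_shape),
            class = "cyto_model")
}

#' Build a convolutional classifier
#'
#' Instantiates randomly initialized (He) weights for a spec whose final
#' layer is a 4-unit dense layer; the index of the highest output score is
#' the predicted class.
#'
#' @param spec an [architecture_spec()].
#' @param seed seed for weight initialization.
#' @return a `cyto_model`.
#' @export
build_cnn <- function(spec, seed = 0L) {
  last <- spec$layers[[length(spec$layers)]]
  if (last$type != "dense")
    stop("spec error: classifier must end with a dense layer")
  build_model(spec, seed)
}

#' Build a convolutional autoencoder
#'
#' @param encoder_spec,decoder_spec mirrored [architecture_spec()]s: the
#'   decoder must map the encoder's output shape back to the encoder's
#'   input shape, and the encoder output must have fewer elements than its
#'   input (a compressing bottleneck).
#' @param seed seed for weight initialization.
#' @return object of class `cyto_autoencoder` with `$encoder` and
#'   `$decoder` models.
#' @export
build_autoencoder <- function(encoder_spec, decoder_spec, seed = 0L) {
  if (!identical(as.integer(decoder_spec$input_shape),
                 as.integer(encoder_spec$output_shape)))
    stop("spec error: decoder input must equal encoder output shape")
  if (!identical(as.integer(decoder_spec$output_shape),
                 as.integer(encoder_spec$input_shape)))
    stop("spec error: decoder must reverse the encoder dimensions")
  if (prod(encoder_spec$output_shape) >= prod(encoder_spec$input_shape))
    stop("spec error: encoder must compress its input")
  structure(list(encoder = build_model(encoder_spec, derive_seed(seed, 1)),
                 decoder = build_model(decoder_spec, derive_seed(seed, 2))),
            class = "cyto_autoencoder")
}

#' @export
print.cyto_model <- function(x, ...) {
  cat(sprintf("<cyto_model '%s'> %s parameters\n", x$spec$name,
              format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pinned reference architectures. Channel widths were solved by
# solve_cnn_widths() (a brute-force search under the structural constraints:
# alternating conv/pool, dense-64 then dense-4 head for the CNN, mirrored
# encoder/decoder for the AE, 20% dropout in the AE-CNN head) so that the
# closed-form totals hit the published budgets exactly:
# 60,772 (CNN), 20,355 (AE), 10,292 (AE-CNN classifier), 30,647 combined.

#' Reference compact CNN classifier (60,772 parameters)
#'
#' 64x64 RGB input; four conv(3x3, valid, ReLU) + 2x2 maxpool blocks with
#' widths 40, 48, 40, 40; flatten (160); dense-64 (ReLU); dense-4.
#'
#' @return an [architecture_spec()].
#' @export
cnn_reference_spec <- function() {
  architecture_spec(
    c(64, 64, 3),
    c(
      unlist(lapply(c(40, 48, 40, 40), function(w) list(
        list(type = "conv", filters = w, kernel = 3, padding = "valid",
             activation = "relu"),
        list(type = "maxpool"))), recursive = FALSE),
      list(list(type = "flatten"),
           list(type = "dense", units = 64, activation = "relu"),
           list(type = "dense", units = 4, activation = "linear"))
    ),
    name = "cnn_reference"
  )
}

#' Reference convolutional autoencoder (20,355 parameters)
#'
#' Mirrored 3 -> 5 -> 30 -> 32 -> 30 -> 5 -> 3 conv stack on 32x32 RGB
#' input, with three 2x2 poolings in the encoder and three nearest-neighbour
#' upsamplings in the decoder; sigmoid output. The 4x4x32 bottleneck (512
#' values) is the compressed representation fed to the downstream
#' classifier.
#'
#' @return list with `encoder` and `decoder` [architecture_spec()]s.
#' @export
ae_reference_spec <- function() {
  enc <- architecture_spec(
    c(32, 32, 3),
    list(
      list(type = "conv", filters = 5, activation = "relu"),
      list(type = "maxpool"),
      list(type = "conv", filters = 30, activation = "relu"),
      list(type = "maxpool"),
      list(type = "conv", filters = 32, activation = "relu"),
      list(type = "maxpool")
    ),
    name = "ae_encoder"
  )
  dec <- architecture_spec(
    c(4, 4, 32),
    list(
      list(type = "upsample"),
      list(type = "conv", filters = 30, activation = "relu"),
      list(type = "upsample"),
      list(type = "conv", filters = 5, activation = "relu"),
      list(type = "upsample"),
      list(type = "conv", filters = 3, activation = "sigmoid")
    ),
    name = "ae_decoder"
  )
  list(encoder = enc, decoder = dec)
}

#' Reference AE-CNN classifier head (10,292 parameters)
#'
#' Operates on the autoencoder bottleneck (4x4x32): conv-24 + pool,
#' conv-12 + pool, flatten, dense-44 (ReLU), dropout 0.20, dense-4.
#'
#' @return an [architecture_spec()].
#' @export
ae_cnn_classifier_spec <- function() {
  architecture_spec(
    c(4, 4, 32),
    list(
      list(type = "conv", filters = 24, activation = "relu"),
      list(type = "maxpool"),
      list(type = "conv", filters = 12, activation = "relu"),
      list(type = "maxpool"),
      list(type = "flatten"),
      list(type = "dense", units = 44, activation = "relu"),
      list(type = "dropout", rate = 0.20),
      list(type = "dense", units = 4, activation = "linear")
    ),
    name = "ae_cnn_classifier"
  )
}

#' Derived size reductions versus the transfer-model average
#'
#' Percentage reduction of a parameter count relative to the mean size of
#' the five published transfer backbones (ResNet50 23,587,712;
#' DenseNet121 7,037,504; ResNet101 42,658,176; ResNet152 58,370,944;
#' EfficientNetB0 4,049,571).
#'
#' @param n_params parameter count(s).
#' @return percentage reduction(s), unrounded.
#' @export
transfer_reduction_pct <- function(n_params) {
  transfer_counts <- c(ResNet50 = 23587712, DenseNet121 = 7037504,
                       ResNet101 = 42658176, ResNet152 = 58370944,
                       EfficientNetB0 = 4049571)
  100 * (1 - n_params / mean(transfer_counts))
}

#' Small CNN for experiments and tests
#'
#' @param resolution input side length.
#' @param widths conv widths (one conv + pool block per entry).
#' @param dense hidden dense width.
#' @param padding conv padding mode.
#' @return an [architecture_spec()].
#' @export
tiny_cnn_spec <- function(resolution = 32, widths = c(8, 16), dense = 32,
                          padding = "same") {
  architecture_spec(
    c(resolution, resolution, 3),
    c(
      unlist(lapply(widths, function(w) list(
        list(type = "conv", filters = w, padding = padding,
             activation = "relu"),
        list(type = "maxpool"))), recursive = FALSE),
      list(list(type = "flatten"),
           list(type = "dense", units = dense, activation = "relu"),
           list(type = "dense", units = 4, activation = "linear"))
    ),
    name = "tiny_cnn"
  )
}

#' Brute-force channel-width solver for a parameter budget
#'
#' Searches conv widths for an alternating conv/pool architecture with a
#' dense head so that the closed-form trainable-parameter total equals a
#' target budget. This is the solver that produced the pinned reference
#' configurations.
#'
#' @param budget target parameter total.
#' @param resolution input side length.
#' @param n_blocks number of conv+pool blocks.
#' @param head_units dense head width(s) before the final dense-4.
#' @param padding conv padding mode.
#' @param width_grid candidate conv widths.
#' @param max_solutions stop after this many hits.
#' @return list of solutions, each a vector of conv widths.
#' @export
solve_cnn_widths <- function(budget, resolution = 64, n_blocks = 4,
                             head_units = 64, padding = "valid",
                             width_grid = c(4, 8, 12, 16, 20, 24, 32, 40, 48, 64),
                             max_solutions = 10L) {
  count_for <- function(widths) {
    cin <- 3L; r <- resolution; tot <- 0
    for (w in widths) {
      tot <- tot + 9 * cin * w + w
      if (padding == "valid") r <- r - 2L
      r <- r %/% 2L
      if (r < 1) return(NA_real_)
      cin <- w
    }
    d <- r * r * cin
    for (u in c(head_units, 4L)) {
      tot <- tot + (d + 1) * u
      d <- u
    }
    tot
  }
  grid <- expand.grid(rep(list(width_grid), n_blocks))
  sols <- list()
  for (i in seq_len(nrow(grid))) {
    w <- as.numeric(grid[i, ])
    ct <- count_for(w)
    if (!is.na(ct) && ct == budget) {
      sols[[length(sols) + 1]] <- w
      if (length(sols) >= max_solutions) break
    }
  }
  sols
}

#' Random-weight stub backbone
#'
#' Stands in for a pretrained transfer backbone: a small fixed feature
#' extractor ending in a dense classification layer. No pretrained weights
#' are involved; real backbones are pluggable via the same interface.
#'
#' @param feature_dim dimensionality of the penultimate feature layer.
#' @param resolution input side length.
#' @param n_classes output dimension of the (replaceable) final layer.
#' @param seed weight seed.
#' @return a `cyto_model` whose final layer is dense.
#' @export
stub_backbone <- function(feature_dim = 8, resolution = 32, n_classes = 4,
                          seed = 0L) {
  spec <- architecture_spec(
    c(resolution, resolution, 3),
    list(
      list(type = "conv", filters = 4, activation = "relu"),
      list(type = "maxpool"),
      list(type = "maxpool"),
      list(type = "flatten"),
      list(type = "dense", units = feature_dim, activation = "relu"),
      list(type = "dense", units = n_classes, activation = "linear")
    ),
    name = "stub_backbone"
  )
  build_model(spec, seed)
}

#' Replace a backbone's classification head
#'
#' Isolates the final fully-connected layer of a backbone, replaces it with
#' a freshly initialized dense layer with `n_classes` outputs, and (in
#' `head_only` mode) freezes every other layer so only the new head trains.
#'
#' @param backbone a `cyto_model` ending in a dense layer.
#' @param n_classes number of output classes.
#' @param mode `"head_only"` (freeze backbone) or `"full"` (fine-tune all).
#' @param seed head initialization seed.
#' @return adapted `cyto_model`.
#' @export
adapt_transfer_head <- function(backbone, n_classes = 4,
                                mode = c("head_only", "full"), seed = 0L) {
  mode <- match.arg(mode)
  nl <- length(backbone$layers)
  if (nl == 0 || backbone$layers[[nl]]$type != "dense")
    stop("adapter error: backbone must end in a dense layer")
  model <- backbone
  head <- model$spec$layers[[nl]]
  head$units <- as.integer(n_classes)
  head$output_shape <- as.integer(n_classes)
  head$activation <- "linear"
  model$spec$layers[[nl]] <- head
  model$spec$output_shape <- as.integer(n_classes)
  model$layers[[nl]] <- with_seed(seed, init_layer(head))
  if (mode == "head_only") {
    for (i in seq_len(nl - 1)) model$layers[[i]]$trainable <- FALSE
  }
  model
}
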