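# Configuration-driven end-to-end experiments and the command-line
# interface.

#' Tiny autoencoder spec pair for experiments
#'
#' A scaled-down mirrored conv autoencoder (two pool/upsample stages) used
#' by the experiment runner at configurable resolution.
#'
#' @param resolution input side length (multiple of 4).
#' @param widths two conv widths (encoder order).
#' @return list with `encoder` and `decoder` specs.
#' @export
tiny_ae_spec <- function(resolution = 32, widths = c(8, 16)) {
  enc <- architecture_spec(
    c(resolution, resolution, 3),
    list(list(type = "conv", filters = widths[1], activation = "relu"),
         list(type = "maxpool"),
         list(type = "conv", filters = widths[2], activation = "relu"),
         list(type = "maxpool")),
    name = "tiny_ae_encoder")
  dec <- architecture_spec(
    c(resolution %/% 4, resolution %/% 4, widths[2]),
    list(list(type = "upsample"),
         list(type = "conv", filters = widths[1], activation = "relu"),
         list(type = "upsample"),
         list(type = "conv", filters = 3, activation = "sigmoid")),
    name = "tiny_ae_decoder")
  list(encoder = enc, decoder = dec)
}

default_experiment_config <- function() {
  list(
    seed = 0L,
    output_dir = NULL,
    dataset = list(counts = c(NILM = 20, LSIL = 20, HSIL = 20, SCC = 20),
                   resolution = 32, target_counts = NULL),
    augmentation = list(balance = TRUE, max_rotation = 25,
                        allow_flips = TRUE),
    split = c(0.65, 0.15, 0.20),
    model = "cnn",
    model_widths = c(8, 16),
    dense_units = 32,
    ensemble_size = 3,
    training = list(epochs = 2, learning_rate = 1e-3, batch_size = 16),
    coral = NULL
  )
}

validate_config <- function(config) {
  def <- default_experiment_config()
  for (nm in names(def)) if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
  for (nm in names(def$dataset))
    if (is.null(config$dataset[[nm]])) config$dataset[[nm]] <- def$dataset[[nm]]
  for (nm in names(def$training))
    if (is.null(config$training[[nm]])) config$training[[nm]] <- def$training[[nm]]
  if (!config$model %in% c("cnn", "ae_cnn", "transfer_stub", "ensemble"))
    stop("config error: unknown model '", config$model, "'")
  counts <- unlist(config$dataset$counts)
  if (is.null(names(counts)) || !all(names(counts) %in% bethesda_classes()))
    stop("config error: dataset$counts must be named with Bethesda classes")
  if (is.null(config$output_dir)) stop("config error: output_dir required")
  if (abs(sum(config$split) - 1) > 1e-8)
    stop("config error: split fractions must sum to 1")
  config
}

#' Run a configuration-driven experiment
#'
#' Executes the full pipeline — simulate, optionally balance, split, train
#' the chosen model (plain CNN, AE-CNN, stub transfer head or majority-vote
#' ensemble), optionally CORAL-adapt against a simulated target domain, and
#' evaluate on the held-out test split — writing a manifest, checkpoint,
#' history CSV, `metrics.json` and a run log with the fully resolved
#' configuration to the output directory. Re-running an identical config
#' reproduces all metrics.
#'
#' @param config list (or path to a YAML file) with fields `seed`,
#'   `output_dir`, `dataset` (`counts`, `resolution`, optional
#'   `target_counts`), `augmentation`, `split`, `model`
#'   (`cnn`/`ae_cnn`/`transfer_stub`/`ensemble`), `training`, optional
#'   `coral` (`lambda`).
#' @return invisibly, a list with the metrics, predictions and artifact
#'   paths.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "run.log")
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  cat(yaml::as.yaml(config), file = file.path(config$output_dir,
                                              "resolved_config.yaml"))
  logline("resolved config written; seed = ", config$seed)

  res <- config$dataset$resolution
  counts <- unlist(config$dataset$counts)
  ds <- synth_dataset(counts, preparation_style("source"),
                      seed = config$seed, resolution = res)
  logline("simulated ", n_images(ds), " source images")
  if (isTRUE(config$augmentation$balance)) {
    pol <- augmentation_policy(config$augmentation$max_rotation,
                               config$augmentation$allow_flips)
    ds <- balance_classes(ds, pol, seed = derive_seed(config$seed, 1))
    logline("balanced to ", n_images(ds), " images")
  }
  ds <- stratified_split(ds, config$split, seed = derive_seed(config$seed, 2))
  manifest <- save_dataset(ds, file.path(config$output_dir, "images"))
  logline("manifest: ", manifest)

  train <- get_split(ds, "train"); val <- get_split(ds, "val")
  test <- get_split(ds, "test")
  tcfg <- training_config(epochs = config$training$epochs,
                          learning_rate = config$training$learning_rate,
                          batch_size = config$training$batch_size,
                          seed = derive_seed(config$seed, 3))
  target <- NULL
  if (!is.null(config$dataset$target_counts)) {
    target <- synth_dataset(unlist(config$dataset$target_counts),
                            preparation_style("target"),
                            seed = derive_seed(config$seed, 4),
                            resolution = res)
    logline("simulated ", n_images(target), " target images")
  }

  models <- list(); scores <- NULL; preds <- NULL
  if (config$model == "cnn" || config$model == "transfer_stub") {
    model <- if (config$model == "cnn") {
      build_cnn(tiny_cnn_spec(res, config$model_widths, config$dense_units),
                seed = derive_seed(config$seed, 5))
    } else {
      adapt_transfer_head(stub_backbone(resolution = res,
                                        seed = derive_seed(config$seed, 5)),
                          seed = derive_seed(config$seed, 6))
    }
    fit <- if (!is.null(config$coral) && !is.null(target)) {
      adapt_train(model, train, target,
                  coral_config(lambda = config$coral$lambda %||% 1),
                  tcfg, val = val)
    } else {
      train_classifier(model, train, val, tcfg)
    }
    models <- list(fit$model)
    utils::write.csv(fit$history,
                     file.path(config$output_dir, "history.csv"),
                     row.names = FALSE)
    scores <- predict_scores(fit$model, test)
    preds <- bethesda_factor(max.col(scores, "first"))
  } else if (config$model == "ae_cnn") {
    sp <- tiny_ae_spec(res, config$model_widths)
    ae <- build_autoencoder(sp$encoder, sp$decoder,
                            seed = derive_seed(config$seed, 5))
    ae_fit <- train_autoencoder(ae, train, val, training_config(
      "ae", epochs = config$training$epochs,
      batch_size = config$training$batch_size,
      seed = derive_seed(config$seed, 7)))
    enc <- ae_fit$ae$encoder
    bshape <- enc$spec$output_shape
    head_spec <- architecture_spec(bshape, list(
      list(type = "conv", filters = config$model_widths[1],
           activation = "relu"),
      list(type = "maxpool"),
      list(type = "flatten"),
      list(type = "dense", units = config$dense_units, activation = "relu"),
      list(type = "dropout", rate = 0.20),
      list(type = "dense", units = 4, activation = "linear")),
      name = "ae_cnn_head")
    head <- build_cnn(head_spec, seed = derive_seed(config$seed, 8))
    fit <- train_classifier(head, encode_dataset(enc, train),
                            encode_dataset(enc, val), tcfg)
    models <- list(list(encoder = enc, head = fit$model))
    utils::write.csv(rbind(
      cbind(stage = "ae", ae_fit$history[, c("epoch", "train_loss", "val_loss")]),
      cbind(stage = "classifier", fit$history[, c("epoch", "train_loss", "val_loss")])),
      file.path(config$output_dir, "history.csv"), row.names = FALSE)
    scores <- model_forward(fit$model, encode_dataset(enc, test)$x)
    preds <- bethesda_factor(max.col(scores, "first"))
  } else {  # ensemble
    fits <- lapply(seq_len(config$ensemble_size), function(k) {
      m <- build_cnn(tiny_cnn_spec(res, config$model_widths,
                                   config$dense_units),
                     seed = derive_seed(config$seed, 50, k))
      cfg_k <- tcfg; cfg_k$seed <- derive_seed(config$seed, 60, k)
      train_classifier(m, train, val, cfg_k)
    })
    models <- lapply(fits, `[[`, "model")
    utils::write.csv(fits[[1]]$history,
                     file.path(config$output_dir, "history.csv"),
                     row.names = FALSE)
    preds <- ensemble_predict(models, test)
    scores <- Reduce(`+`, lapply(models, function(m)
      softmax(predict_scores(m, test)))) / length(models)
  }
  ckpt <- file.path(config$output_dir, "checkpoint.rds")
  save_model(if (length(models) == 1) models[[1]] else models, ckpt)

  truth <- bethesda_factor(test$meta$label)
  cm <- confusion_matrix(truth, preds)
  rep_ <- classification_report(cm)
  auc <- tryCatch(roc_auc(truth, scores)$auc, error = function(e) NA_real_)
  metrics <- list(model = config$model, n_test = length(truth),
                  accuracy = rep_$accuracy, precision = rep_$precision,
                  recall = rep_$recall, f1 = rep_$f1,
                  fpr = rep_$fpr, fnr = rep_$fnr, auc = auc,
                  confusion = unname(as.matrix(cm)))
  jsonlite::write_json(metrics, file.path(config$output_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  logline(sprintf("test accuracy %.4f", rep_$accuracy))
  invisible(list(metrics = metrics, predictions = preds, scores = scores,
                 models = models, manifest = manifest,
                 dir = config$output_dir))
}

parse_cli_args <- function(args) {
  out <- list(positional = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]; i <- i + 2
      } else {
        out[[key]] <- TRUE; i <- i + 1
      }
    } else {
      out$positional <- c(out$positional, a); i <- i + 1
    }
  }
  out
}

parse_counts <- function(s) {
  # "NILM=613,LSIL=113,HSIL=163,SCC=74"
  kv <- strsplit(strsplit(s, ",")[[1]], "=")
  stats::setNames(as.integer(vapply(kv, `[`, "", 2)),
                  vapply(kv, `[`, "", 1))
}

#' Command-line interface
#'
#' Dispatches the `cytocoral` subcommands: `simulate`, `augment`, `split`,
#' `train`, `adapt`, `ensemble-eval`, `evaluate`, `consistency`,
#' `saliency`, `run`. Invoked by the installed `cytocoral` script
#' (`inst/cli/cytocoral`). Returns the exit status (0 on success).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cyto_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) stop("usage: cytocoral <subcommand> [--options]")
    cmd <- args[1]
    opt <- parse_cli_args(args[-1])
    seed <- as.integer(opt$seed %||% 0)
    switch(cmd,
      simulate = {
        counts <- parse_counts(opt$counts %||% "NILM=10,LSIL=10,HSIL=10,SCC=10")
        style <- preparation_style(opt$domain %||% "source")
        ds <- synth_dataset(counts, style, seed = seed,
                            resolution = as.integer(opt$resolution %||% 96))
        message("manifest: ", save_dataset(ds, opt$out %||% "."))
      },
      augment = {
        ds <- load_dataset(opt$manifest)
        ds <- balance_classes(ds, augmentation_policy(), seed = seed)
        message("manifest: ", save_dataset(ds, opt$out %||% dirname(opt$manifest)))
      },
      split = {
        ds <- load_dataset(opt$manifest)
        ds <- stratified_split(ds, seed = seed)
        message("manifest: ", save_dataset(ds, dirname(opt$manifest)))
      },
      run = {
        cfg <- yaml::read_yaml(opt$config)
        if (!is.null(opt$out)) cfg$output_dir <- opt$out
        run_experiment(cfg)
      },
      train = ,
      adapt = {
        cfg <- default_experiment_config()
        cfg$output_dir <- opt$out %||% "cytocoral_run"
        cfg$seed <- seed
        cfg$training$epochs <- as.integer(opt$epochs %||% 2)
        if (cmd == "adapt") {
          cfg$dataset$target_counts <- cfg$dataset$counts
          cfg$coral <- list(lambda = if (identical(opt$lambda, "auto"))
            "auto" else as.numeric(opt$lambda %||% 1))
        }
        run_experiment(cfg)
      },
      `ensemble-eval` = {
        models <- lapply(strsplit(opt$models, ",")[[1]], load_model)
        ds <- load_dataset(opt$manifest)
        preds <- ensemble_predict(models, ds)
        cm <- confusion_matrix(bethesda_factor(ds$meta$label), preds)
        print(classification_report(cm))
      },
      evaluate = {
        model <- load_model(opt$model)
        ds <- load_dataset(opt$manifest)
        sc <- predict_scores(model, ds)
        truth <- bethesda_factor(ds$meta$label)
        cm <- confusion_matrix(truth, bethesda_factor(max.col(sc, "first")))
        print(classification_report(cm))
      },
      consistency = {
        runs <- as.integer(opt$runs %||% 5)
        cfg <- default_experiment_config()
        cfg$training$epochs <- as.integer(opt$epochs %||% 2)
        print(consistency_study(function(s) {
          cfg$seed <- s
          cfg$output_dir <- file.path(tempdir(), paste0("consist", s))
          run_experiment(cfg)$metrics$accuracy
        }, n_runs = runs))
      },
      saliency = {
        model <- load_model(opt$model)
        ds <- load_dataset(opt$manifest)
        sal <- gradient_saliency(model, ds$images[[1]])
        out <- opt$out %||% "saliency.png"
        png::writePNG(sal, out)
        message("saliency map: ", out)
      },
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
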