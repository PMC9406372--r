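#' Construct a labelled image dataset
#'
#' A `cyto_dataset` pairs a list of images with a metadata table holding, per
#' image: `id`, `label` (Bethesda class), `domain` (`source`/`target`),
#' `split` (train/val/test or empty), and augmentation provenance
#' (`source_id`, `transform`, both `NA` for originals).
#'
#' @param images list of h x w x 3 arrays.
#' @param labels Bethesda labels, one per image.
#' @param domain single domain tag or vector.
#' @param split optional split tags.
#' @param meta optional full metadata data.frame (overrides other args).
#' @return object of class `cyto_dataset`.
#' @export
cyto_dataset <- function(images, labels = NULL, domain = "source",
                         split = NULL, meta = NULL) {
  n <- length(images)
  if (is.null(meta)) {
    labels <- if (n == 0) character(0) else as.character(bethesda_factor(labels))
    meta <- data.frame(
      id = if (n > 0) sprintf("img%05d", seq_len(n)) else character(0),
      label = labels,
      domain = rep_len(as.character(domain), n),
      split = if (is.null(split)) rep("", n) else rep_len(as.character(split), n),
      source_id = rep(NA_character_, n),
      transform = rep(NA_character_, n),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(meta) == n)
  structure(list(images = images, meta = meta), class = "cyto_dataset")
}

#' @export
print.cyto_dataset <- function(x, ...) {
  cat(sprintf("<cyto_dataset> %d images\n", length(x$images)))
  if (nrow(x$meta) > 0) {
    print(table(label = x$meta$label, domain = x$meta$domain))
    if (any(nzchar(x$meta$split)))
      print(table(split = x$meta$split))
  }
  invisible(x)
}

#' Number of images in a dataset
#' @param dataset a `cyto_dataset`.
#' @export
n_images <- function(dataset) length(dataset$images)

#' Class counts of a dataset
#' @param dataset a `cyto_dataset`.
#' @return named integer vector over `bethesda_classes()`.
#' @export
class_counts <- function(dataset) {
  tab <- table(factor(dataset$meta$label, levels = bethesda_classes()))
  stats::setNames(as.integer(tab), names(tab))
}

subset_dataset <- function(dataset, idx) {
  cyto_dataset(dataset$images[idx], meta = dataset$meta[idx, , drop = FALSE])
}

#' Save a dataset to disk
#'
#' Writes one PNG per image plus `manifest.csv` with columns
#' `path,label,domain,split`. Ground-truth masks are not persisted.
#'
#' @param dataset a `cyto_dataset`.
#' @param dir output directory (created if missing).
#' @return path to the manifest, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_images(dataset)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, paste0(dataset$meta$id[i], ".png"))
    png::writePNG(unclass_image(dataset$images[[i]]), paths[i])
  }
  man <- data.frame(path = basename(paths),
                    label = dataset$meta$label,
                    domain = dataset$meta$domain,
                    split = dataset$meta$split,
                    stringsAsFactors = FALSE)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' Load a dataset from a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by [save_dataset()]
#'   (columns `path,label,domain,split`; image paths relative to the
#'   manifest's directory).
#' @return a `cyto_dataset`.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("path", "label", "domain", "split")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ","))
  if (nrow(man) == 0) {
    return(cyto_dataset(list(), character(0)))
  }
  bethesda_factor(man$label)  # validates; unknown label -> error
  base <- dirname(manifest_path)
  imgs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    fp <- file.path(base, man$path[i])
    if (!file.exists(fp)) stop("image file missing: ", fp)
    px <- png::readPNG(fp)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
    if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
    im <- array(as.numeric(px), dim = dim(px))
    attr(im, "label") <- man$label[i]
    attr(im, "domain") <- man$domain[i]
    imgs[[i]] <- im
  }
  ds <- cyto_dataset(imgs, labels = man$label, domain = man$domain,
                     split = man$split)
  ds$meta$id <- sub("\\.png$", "", basename(man$path))
  ds
}
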