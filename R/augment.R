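#' Augmentation policy
#'
#' Controls the space of admissible duplicate-free transforms. Rotations are
#' discretized to whole degrees in `[-max_rotation, max_rotation]` so that
#' the number of distinct transforms per source image is countable:
#' `(2 * max_rotation + 1) * (flip combinations) - 1` (the identity is
#' excluded). Excessive rotation degrades multi-cell images whose
#' information extends to the borders, so `max_rotation` is capped at 45
#' degrees; the default of 25 is deliberately conservative.
#'
#' @param max_rotation maximum absolute rotation in whole degrees (<= 45).
#' @param allow_flips allow horizontal/vertical flips.
#' @param fill_mode `"reflect"` (default) or `"edge"`; how rotation fills
#'   pixels sampled outside the frame. Reflection avoids black corners that
#'   would be a trivially learnable artifact.
#' @return object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(max_rotation = 25L, allow_flips = TRUE,
                                fill_mode = c("reflect", "edge")) {
  fill_mode <- match.arg(fill_mode)
  max_rotation <- as.integer(max_rotation)
  if (max_rotation < 0 || max_rotation > 45)
    stop("max_rotation must be in [0, 45] degrees")
  structure(list(max_rotation = max_rotation, allow_flips = allow_flips,
                 fill_mode = fill_mode),
            class = "augmentation_policy")
}

#' A single augmentation transform
#'
#' @param rotation_degrees signed whole-degree rotation.
#' @param flip_horizontal,flip_vertical logical flips (applied before
#'   rotation).
#' @return object of class `augment_transform`.
#' @export
augment_transform <- function(rotation_degrees = 0L, flip_horizontal = FALSE,
                              flip_vertical = FALSE) {
  structure(list(rotation_degrees = as.integer(rotation_degrees),
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical)),
            class = "augment_transform")
}

is_identity_transform <- function(tr) {
  tr$rotation_degrees == 0L && !tr$flip_horizontal && !tr$flip_vertical
}

transform_key <- function(tr) {
  sprintf("r%+d_h%d_v%d", tr$rotation_degrees,
          as.integer(tr$flip_horizontal), as.integer(tr$flip_vertical))
}

# number of distinct non-identity transforms under a policy
transform_capacity <- function(policy) {
  (2L * policy$max_rotation + 1L) * (if (policy$allow_flips) 4L else 1L) - 1L
}

rotate_image <- function(img, degrees, fill_mode = "reflect") {
  if (degrees %% 360 == 0) return(img)
  d <- dim(img)
  a <- degrees * pi / 180
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  ys <- matrix(seq_len(d[1]), d[1], d[2]) - cy
  xs <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cx
  # inverse map: rotate output coords by -angle into the input frame
  sy <- ys * cos(a) - xs * sin(a) + cy
  sx <- ys * sin(a) + xs * cos(a) + cx
  reflect <- function(v, n) {
    # reflect indices into [1, n] (period 2n - 2)
    v <- abs(v - 1) %% (2 * n - 2)
    ifelse(v > n - 1, 2 * n - 2 - v, v) + 1
  }
  edge <- function(v, n) pmin(pmax(v, 1), n)
  fixup <- if (fill_mode == "reflect") reflect else edge
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  i00 <- cbind(as.vector(fixup(y0, d[1])), as.vector(fixup(x0, d[2])))
  i01 <- cbind(i00[, 1], as.vector(fixup(x0 + 1, d[2])))
  i10 <- cbind(as.vector(fixup(y0 + 1, d[1])), i00[, 2])
  i11 <- cbind(i10[, 1], i01[, 2])
  out <- array(0, dim = d)
  for (ch in seq_len(d[3])) {
    p <- img[, , ch]
    v <- p[i00] * as.vector((1 - wy) * (1 - wx)) +
         p[i01] * as.vector((1 - wy) * wx) +
         p[i10] * as.vector(wy * (1 - wx)) +
         p[i11] * as.vector(wy * wx)
    out[, , ch] <- matrix(v, d[1], d[2])
  }
  clip01(out)
}

#' Apply an augmentation transform to an image
#'
#' Flips are applied first, then rotation with bilinear resampling and
#' border fill per the policy. Shape, intensity range and label/domain
#' attributes are preserved.
#'
#' @param image h x w x 3 array.
#' @param transform an [augment_transform()].
#' @param policy an [augmentation_policy()]; the transform's rotation must
#'   lie within the policy range.
#' @param as_copy when `TRUE` the call creates an augmented duplicate, and
#'   the identity transform is rejected (duplicates must differ from their
#'   source).
#' @return transformed image.
#' @export
augment_image <- function(image, transform, policy = augmentation_policy(),
                          as_copy = FALSE) {
  stopifnot_image(image)
  if (as_copy && is_identity_transform(transform))
    stop("identity transform is excluded when creating augmented copies")
  if (abs(transform$rotation_degrees) > policy$max_rotation)
    stop("rotation outside the policy range")
  if ((transform$flip_horizontal || transform$flip_vertical) &&
      !policy$allow_flips)
    stop("flips are disabled by the policy")
  at <- attributes(image)
  out <- unclass_image(image)
  if (transform$flip_horizontal) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  if (transform$flip_vertical) out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
  if (transform$rotation_degrees != 0L)
    out <- rotate_image(out, transform$rotation_degrees, policy$fill_mode)
  for (nm in setdiff(names(at), c("dim", "cell_mask", "nuclear_mask")))
    attr(out, nm) <- at[[nm]]
  out
}

sample_transform <- function(policy) {
  repeat {
    tr <- augment_transform(
      rotation_degrees = sample.int(2L * policy$max_rotation + 1L, 1L) -
        policy$max_rotation - 1L,
      flip_horizontal = policy$allow_flips && stats::runif(1) < 0.5,
      flip_vertical = policy$allow_flips && stats::runif(1) < 0.5
    )
    if (!is_identity_transform(tr)) return(tr)
  }
}

#' Balance class sizes by duplicate-free augmentation
#'
#' Augments every minority class up to the size of the largest class (or an
#' explicit `target`) by duplicating randomly chosen originals under
#' randomized rotation/flip transforms. Originals are retained unmodified;
#' no two augmented copies of the same source image share a transform, and
#' the identity transform is never used, so all produced images are
#' distinct.
#'
#' @param dataset a `cyto_dataset` with at least one image per class
#'   present in it.
#' @param policy an [augmentation_policy()].
#' @param seed integer seed.
#' @param target optional explicit per-class target count (defaults to the
#'   maximum class count).
#' @return balanced `cyto_dataset`; augmented rows carry `source_id` and a
#'   `transform` key.
#' @export
balance_classes <- function(dataset, policy = augmentation_policy(),
                            seed = 0L, target = NULL) {
  cc <- class_counts(dataset)
  present <- names(cc)[cc > 0]
  if (length(present) == 0) stop("dataset is empty")
  if (is.null(target)) target <- max(cc)
  need <- target - cc[present]
  if (any(need < 0)) stop("target below an existing class count")
  cap <- transform_capacity(policy)
  for (lab in present) {
    n_src <- cc[[lab]]
    if (need[[lab]] > n_src * cap)
      stop(sprintf(
        "capacity error: class %s needs %d augmented copies but only %d distinct (source, transform) pairs exist",
        lab, need[[lab]], n_src * cap))
  }
  if (all(need == 0)) return(dataset)

  imgs <- dataset$images
  meta <- dataset$meta
  with_seed(seed, {
    for (lab in present) {
      k <- need[[lab]]
      if (k == 0) next
      src_idx <- which(dataset$meta$label == lab)
      used <- stats::setNames(vector("list", length(src_idx)),
                              as.character(src_idx))
      made <- 0L
      while (made < k) {
        s <- src_idx[sample.int(length(src_idx), 1L)]
        key_used <- used[[as.character(s)]]
        if (length(key_used) >= cap) next  # this source is exhausted
        repeat {
          tr <- sample_transform(policy)
          if (!(transform_key(tr) %in% key_used)) break
        }
        used[[as.character(s)]] <- c(key_used, transform_key(tr))
        new_img <- augment_image(dataset$images[[s]], tr, policy)
        imgs[[length(imgs) + 1L]] <- new_img
        meta <- rbind(meta, data.frame(
          id = sprintf("%s_aug%04d", dataset$meta$id[s], length(key_used) + 1L),
          label = lab, domain = dataset$meta$domain[s], split = "",
          source_id = dataset$meta$id[s], transform = transform_key(tr),
          stringsAsFactors = FALSE))
        made <- made + 1L
      }
    }
  })
  cyto_dataset(imgs, meta = meta)
}

#' Stratified train/validation/test split
#'
#' Shuffles each class independently and assigns, per class of size `m`,
#' `round(test * m)` images to test and `round(val * m)` to validation
#' (half-away-from-zero rounding), with the remainder as training data.
#' With the default 65:15:20 fractions this reproduces the canonical
#' 398/92/123 per-class partition of a 613-image class.
#'
#' @param dataset a `cyto_dataset`.
#' @param fractions numeric triple (train, val, test) summing to 1.
#' @param seed integer seed for the shuffle.
#' @return the dataset with `split` filled in (`"train"`, `"val"`, `"test"`).
#' @export
stratified_split <- function(dataset, fractions = c(0.65, 0.15, 0.20),
                             seed = 0L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  meta <- dataset$meta
  split <- rep("", nrow(meta))
  with_seed(seed, {
    for (lab in unique(meta$label)) {
      idx <- which(meta$label == lab)
      m <- length(idx)
      if (m < 3 && all(fractions > 0))
        warning(sprintf("class %s has fewer than 3 images; degenerate split", lab))
      idx <- idx[sample.int(m)]
      n_test <- as.integer(round_half_up(fractions[3] * m))
      n_val <- as.integer(round_half_up(fractions[2] * m))
      n_val <- min(n_val, m - n_test)
      split[idx[seq_len(n_test)]] <- "test"
      if (n_val > 0) split[idx[n_test + seq_len(n_val)]] <- "val"
      rest <- idx[setdiff(seq_len(m), seq_len(n_test + n_val))]
      split[rest] <- "train"
    }
  })
  dataset$meta$split <- split
  dataset
}

#' Extract one split partition
#'
#' @param dataset a split `cyto_dataset`.
#' @param which one of `"train"`, `"val"`, `"test"`.
#' @return the corresponding `cyto_dataset` subset.
#' @export
get_split <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  subset_dataset(dataset, dataset$meta$split == which)
}
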