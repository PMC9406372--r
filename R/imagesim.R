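#' Class-conditional nuclear morphology parameters
#'
#' Returns the rendering parameters for one Bethesda class. The key cytologic
#' signal is the nuclear-to-cytoplasmic area ratio, which increases strictly
#' with lesion severity, together with increasing nuclear boundary
#' irregularity and clustering tendency. Defaults were chosen once so that a
#' simple threshold on measured nuclear-area fraction separates the extreme
#' classes and a small CNN can learn all four.
#'
#' @param label a single Bethesda label.
#' @return list with `cell_count_range`, `nuclear_area_fraction_mean`,
#'   `nuclear_area_fraction_sd`, `nuclear_irregularity`, `cluster_tendency`,
#'   `nucleus_darkness`.
#' @export
morphology_params <- function(label) {
  f <- bethesda_factor(label)
  if (length(f) != 1L) stop("label must be a single Bethesda class")
  i <- as.integer(f)
  naf <- c(0.10, 0.20, 0.32, 0.45)
  irr <- c(0.04, 0.12, 0.25, 0.40)
  clu <- c(0.10, 0.20, 0.35, 0.50)
  dark <- c(0.00, 0.08, 0.16, 0.24)
  stopifnot(all(diff(naf) > 0), all(naf > 0 & naf < 1))
  list(
    cell_count_range = c(6L, 12L),
    nuclear_area_fraction_mean = naf[i],
    nuclear_area_fraction_sd = 0.03,
    nuclear_irregularity = irr[i],
    cluster_tendency = clu[i],
    nucleus_darkness = dark[i]
  )
}

#' Preparation style (imaging domain)
#'
#' Describes the appearance of one liquid-based preparation protocol. The
#' `source` style is the identity baseline; the default `target` style
#' emulates a different preparation/staining protocol via a stain hue
#' rotation, a contrast change, a lower cell density and stronger background
#' texture, producing a measurable covariate shift between domains.
#'
#' @param domain `"source"` or `"target"`.
#' @param stain_hue_shift hue rotation in degrees.
#' @param contrast_scale multiplicative contrast about mid-grey.
#' @param density_scale multiplier on the number of rendered cells.
#' @param background_texture background noise amplitude multiplier
#'   (1 = baseline; the shift adds noise proportional to the excess over 1).
#' @return object of class `preparation_style`.
#' @export
preparation_style <- function(domain = c("source", "target"),
                              stain_hue_shift = NULL,
                              contrast_scale = NULL,
                              density_scale = NULL,
                              background_texture = NULL) {
  domain <- match.arg(domain)
  def <- if (domain == "source") {
    list(stain_hue_shift = 0, contrast_scale = 1,
         density_scale = 1, background_texture = 1)
  } else {
    list(stain_hue_shift = 20, contrast_scale = 1.3,
         density_scale = 0.7, background_texture = 2)
  }
  st <- list(
    domain = domain,
    stain_hue_shift = if (is.null(stain_hue_shift)) def$stain_hue_shift else stain_hue_shift,
    contrast_scale = if (is.null(contrast_scale)) def$contrast_scale else contrast_scale,
    density_scale = if (is.null(density_scale)) def$density_scale else density_scale,
    background_texture = if (is.null(background_texture)) def$background_texture else background_texture
  )
  stopifnot(st$contrast_scale > 0, st$density_scale > 0,
            st$background_texture >= 0)
  structure(st, class = "preparation_style")
}

is_appearance_baseline <- function(style) {
  style$stain_hue_shift == 0 && style$contrast_scale == 1 &&
    style$background_texture <= 1
}

# hue rotation about the grey axis (standard luminance-preserving matrix)
hue_rotation_matrix <- function(degrees) {
  a <- degrees * pi / 180
  c_ <- cos(a); s <- sin(a)
  matrix(c(
    0.213 + c_ * 0.787 - s * 0.213, 0.715 - c_ * 0.715 - s * 0.715, 0.072 - c_ * 0.072 + s * 0.928,
    0.213 - c_ * 0.213 + s * 0.143, 0.715 + c_ * 0.285 + s * 0.140, 0.072 - c_ * 0.072 - s * 0.283,
    0.213 - c_ * 0.213 - s * 0.787, 0.715 - c_ * 0.715 + s * 0.715, 0.072 + c_ * 0.928 + s * 0.072
  ), nrow = 3, byrow = TRUE)
}

#' Apply a cross-preparation appearance shift to an image
#'
#' Applies the style's stain hue rotation, contrast scaling and extra
#' background noise, clipping the result to `[0, 1]`. A baseline (source)
#' style is the exact identity. Cell density is a generation-time property
#' and is not altered here. The label and any ground-truth masks are
#' preserved.
#'
#' @param image an h x w x 3 array (optionally a `cyto_image`).
#' @param style a [preparation_style()].
#' @param seed optional seed for the noise term; when `NULL` the current RNG
#'   stream is used.
#' @return shifted image with the input's attributes, `domain` set to the
#'   style's domain.
#' @export
apply_preparation_shift <- function(image, style, seed = NULL) {
  stopifnot_image(image)
  at <- attributes(image)
  if (is_appearance_baseline(style)) {
    attr(image, "domain") <- style$domain
    return(image)
  }
  d <- dim(image)
  px <- matrix(as.numeric(image), ncol = 3L)  # (h*w) x 3, column-major per channel
  if (style$stain_hue_shift != 0) {
    px <- px %*% t(hue_rotation_matrix(style$stain_hue_shift))
  }
  if (style$contrast_scale != 1) {
    px <- (px - 0.5) * style$contrast_scale + 0.5
  }
  out <- array(px, dim = d)
  extra <- style$background_texture - 1
  if (extra > 0) {
    noise_one <- function() array(stats::rnorm(prod(d), 0, 0.02 * extra), dim = d)
    out <- out + if (is.null(seed)) noise_one() else with_seed(seed, noise_one())
  }
  out <- clip01(out)
  for (nm in setdiff(names(at), c("dim"))) attr(out, nm) <- at[[nm]]
  attr(out, "domain") <- style$domain
  out
}

# Draw per-cell geometry/colour parameters from a dedicated subseed so that
# density truncation across domains leaves shared cells bit-identical.
draw_cell <- function(seed, res, mp) {
  with_seed(seed, {
    a <- res * stats::runif(1, 0.075, 0.135)        # cytoplasm semi-axes
    b <- a * stats::runif(1, 0.6, 1.0)
    th <- stats::runif(1, 0, pi)
    frac <- min(0.9, max(0.02, stats::rnorm(1, mp$nuclear_area_fraction_mean,
                                            mp$nuclear_area_fraction_sd)))
    r_nuc <- sqrt(frac * a * b)                      # nucleus base radius
    harm <- stats::rnorm(4, 0, 1)                    # boundary irregularity
    phase <- stats::runif(4, 0, 2 * pi)
    off <- stats::runif(2, -0.2, 0.2) * c(a, b)      # nucleus offset in cell
    cyto_col <- c(0.75, 0.62, 0.78) + stats::runif(3, -0.05, 0.05)
    nuc_col <- c(0.38, 0.22, 0.52) - mp$nucleus_darkness + stats::runif(3, -0.03, 0.03)
    place <- stats::runif(3)                         # centre + cluster draw
    list(a = a, b = b, th = th, r_nuc = r_nuc, harm = harm, phase = phase,
         off = off, cyto_col = clip01(cyto_col), nuc_col = clip01(nuc_col),
         place = place)
  })
}

#' Synthesize one multi-cell cytology image
#'
#' Renders a seeded synthetic microscopy-style image: a textured background
#' with several cells, each a cytoplasm ellipse containing a darker nucleus
#' whose relative area, boundary irregularity and chromatin darkness depend
#' on the Bethesda class. Ground-truth cytoplasm and nucleus masks are
#' attached as attributes. Deterministic for fixed `(label, style, seed)`.
#'
#' @param label Bethesda class label.
#' @param style a [preparation_style()]; geometry depends only on the style's
#'   `density_scale`, appearance on its remaining fields.
#' @param seed non-negative integer seed.
#' @param resolution image side length in pixels (square output, >= 16).
#' @return `cyto_image`: h x w x 3 array in `[0,1]` with attributes `label`,
#'   `domain`, `cell_mask`, `nuclear_mask`.
#' @export
synth_cell_image <- function(label, style = preparation_style("source"),
                             seed = 0L, resolution = 96L) {
  f <- bethesda_factor(label)
  if (length(f) != 1L) stop("label must be a single Bethesda class")
  stopifnot(seed >= 0, resolution >= 16)
  mp <- morphology_params(f)
  res <- as.integer(resolution)

  n_base <- with_seed(derive_seed(seed, 0),
                      sample(seq(mp$cell_count_range[1], mp$cell_count_range[2]), 1))
  n_cells <- max(1L, as.integer(round_half_up(n_base * style$density_scale)))

  img <- array(rep(c(0.93, 0.89, 0.94), each = res * res), dim = c(res, res, 3))
  img <- img + with_seed(derive_seed(seed, 1),
                         array(stats::rnorm(res * res * 3, 0, 0.02), dim = c(res, res, 3)))
  cell_mask <- matrix(FALSE, res, res)
  nuc_mask <- matrix(FALSE, res, res)

  ys <- matrix(seq_len(res), res, res)        # row coordinate
  xs <- matrix(seq_len(res), res, res, byrow = TRUE)
  centres <- matrix(numeric(0), ncol = 2)

  for (i in seq_len(n_cells)) {
    cl <- draw_cell(derive_seed(seed, 10 + i), res, mp)
    margin <- max(cl$a, cl$b)
    if (nrow(centres) > 0 && cl$place[3] < mp$cluster_tendency) {
      base <- centres[1 + (i %% nrow(centres)), ]
      cx <- min(max(base[1] + (cl$place[1] - 0.5) * 3 * cl$a, margin), res - margin)
      cy <- min(max(base[2] + (cl$place[2] - 0.5) * 3 * cl$b, margin), res - margin)
    } else {
      cx <- margin + cl$place[1] * (res - 2 * margin)
      cy <- margin + cl$place[2] * (res - 2 * margin)
    }
    centres <- rbind(centres, c(cx, cy))

    dx <- xs - cx; dy <- ys - cy
    u <- dx * cos(cl$th) + dy * sin(cl$th)
    v <- -dx * sin(cl$th) + dy * cos(cl$th)
    in_cyto <- (u / cl$a)^2 + (v / cl$b)^2 <= 1

    ndx <- dx - cl$off[1]; ndy <- dy - cl$off[2]
    rho <- sqrt(ndx^2 + ndy^2)
    ang <- atan2(ndy, ndx)
    rb <- cl$r_nuc * (1 + mp$nuclear_irregularity *
                        (0.35 * cl$harm[1] * cos(2 * ang + cl$phase[1]) +
                         0.30 * cl$harm[2] * cos(3 * ang + cl$phase[2]) +
                         0.20 * cl$harm[3] * cos(4 * ang + cl$phase[3]) +
                         0.15 * cl$harm[4] * cos(5 * ang + cl$phase[4])))
    in_nuc <- in_cyto & (rho <= pmax(rb, 1))

    for (ch in 1:3) {
      p <- img[, , ch]
      p[in_cyto] <- cl$cyto_col[ch]
      p[in_nuc] <- cl$nuc_col[ch]
      img[, , ch] <- p
    }
    cell_mask <- cell_mask | in_cyto
    nuc_mask <- (nuc_mask & !in_cyto) | in_nuc
  }

  img <- clip01(img)
  attr(img, "label") <- as.character(f)
  attr(img, "cell_mask") <- cell_mask
  attr(img, "nuclear_mask") <- nuc_mask
  img <- apply_preparation_shift(img, style, seed = derive_seed(seed, 2))
  class(img) <- c("cyto_image", class(img))
  img
}

#' Measured nuclear-area fraction of a synthetic image
#'
#' Ratio of nucleus pixels to cell pixels using the generator's ground-truth
#' masks. This is the morphological quantity whose class-conditional mean
#' increases strictly with severity.
#'
#' @param image a `cyto_image` carrying mask attributes.
#' @return scalar in `[0, 1]`.
#' @export
nuclear_area_fraction <- function(image) {
  cm <- attr(image, "cell_mask"); nm <- attr(image, "nuclear_mask")
  if (is.null(cm) || is.null(nm)) stop("image has no ground-truth masks")
  if (sum(cm) == 0) return(0)
  sum(nm) / sum(cm)
}

#' Generate a labelled synthetic dataset
#'
#' @param class_counts named integer vector (names in `bethesda_classes()`),
#'   images to generate per class; all counts >= 0.
#' @param style a [preparation_style()].
#' @param seed master seed; per-image seeds are derived deterministically.
#' @param resolution image side length in pixels.
#' @return a [cyto_dataset()] with one row of metadata per image.
#' @export
synth_dataset <- function(class_counts, style = preparation_style("source"),
                          seed = 0L, resolution = 96L) {
  lv <- bethesda_classes()
  if (is.null(names(class_counts)) || !all(names(class_counts) %in% lv))
    stop("class_counts must be named with Bethesda classes")
  if (any(class_counts < 0)) stop("class counts must be non-negative")
  imgs <- list(); labs <- character(0)
  for (ci in seq_along(lv)) {
    n <- if (lv[ci] %in% names(class_counts)) class_counts[[lv[ci]]] else 0L
    if (is.na(n)) n <- 0L
    for (i in seq_len(n)) {
      imgs[[length(imgs) + 1L]] <-
        synth_cell_image(lv[ci], style, seed = derive_seed(seed, ci, i),
                         resolution = resolution)
      labs <- c(labs, lv[ci])
    }
  }
  cyto_dataset(imgs, labels = labs, domain = style$domain)
}

#' Pooled raw-pixel features
#'
#' Block-averages each image onto a coarse `grid x grid x 3` summary and
#' flattens it, giving a cheap fixed-length feature vector used to measure
#' raw-pixel domain shift (e.g. with [coral_loss()]).
#'
#' @param dataset a `cyto_dataset` (or list of images).
#' @param grid pooling grid side length.
#' @return numeric matrix, one row per image, `3 * grid^2` columns.
#' @export
pixel_features <- function(dataset, grid = 4L) {
  imgs <- if (inherits(dataset, "cyto_dataset")) dataset$images else dataset
  t(vapply(imgs, function(im) {
    small <- resize_image(unclass_image(im), grid, grid)
    as.numeric(small)
  }, numeric(3 * grid * grid)))
}

unclass_image <- function(im) {
  array(as.numeric(im), dim = dim(im))
}
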