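#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-item seed derived from a master seed and integer tags.
# Multiplicative hashing on doubles; all intermediates stay below 2^53 and
# the result below 2^31 so it is a valid set.seed() argument.
derive_seed <- function(master, ...) {
  tags <- c(as.numeric(master), as.numeric(c(...)))
  h <- 0
  for (t in tags) h <- ((h * 69069 + t + 1) %% 2147483629)
  as.integer(h %% 2147483587 + 1)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# round() uses banker's rounding; splits and counts need half-away-from-zero.
round_half_up <- function(x) floor(x + 0.5)

stopifnot_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("image must be an h x w x 3 array")
  if (dim(img)[1] < 16L || dim(img)[2] < 16L)
    stop("image must be at least 16 x 16 pixels")
  if (any(!is.finite(img)) || any(img < 0) || any(img > 1))
    stop("image intensities must lie in [0, 1]")
  invisible(img)
}

#' Bilinear image resize
#'
#' @param img h x w x 3 array in `[0,1]`.
#' @param height,width target spatial dimensions.
#' @return resized array, attributes dropped.
#' @export
resize_image <- function(img, height, width) {
  d <- dim(img)
  if (d[1] == height && d[2] == width) {
    return(array(as.numeric(img), dim = d))
  }
  # map output pixel centres into input coordinates (align centres)
  ys <- (seq_len(height) - 0.5) * d[1] / height + 0.5 - 1e-9
  xs <- (seq_len(width) - 0.5) * d[2] / width + 0.5 - 1e-9
  y0 <- pmin(pmax(floor(ys), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(xs), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) {
    p <- img[, , ch]
    a <- p[y0, x0, drop = FALSE]; b <- p[y0, x1, drop = FALSE]
    c_ <- p[y1, x0, drop = FALSE]; dd <- p[y1, x1, drop = FALSE]
    top <- a * outer(rep(1, height), 1 - wx) + b * outer(rep(1, height), wx)
    bot <- c_ * outer(rep(1, height), 1 - wx) + dd * outer(rep(1, height), wx)
    out[, , ch] <- top * (1 - wy) + bot * wy
  }
  out
}
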