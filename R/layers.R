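# Neural-network primitives.
#
# Batch tensors use dimension order (height, width, channels, batch).
# Convolution follows the deep-learning convention: cross-correlation, no
# kernel flip, unit stride; "valid" or zero-padded "same" spatial modes.

#' Rectified linear unit
#'
#' `f(x) = max(0, x)`, elementwise.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape with negative entries set to 0.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

activate <- function(x, kind) {
  switch(kind,
         relu = relu(x),
         linear = x,
         sigmoid = 1 / (1 + exp(-x)),
         stop("unknown activation: ", kind))
}

activate_grad <- function(z, kind) {
  switch(kind,
         relu = (z > 0) * 1,
         linear = array(1, dim = dim(z) %||% length(z)),
         sigmoid = { s <- 1 / (1 + exp(-z)); s * (1 - s) },
         stop("unknown activation: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.im2col_cache <- new.env(parent = emptyenv())

# im2col index matrix for a padded input of dims (H, W, C, N) and kernel k.
# Rows enumerate (out_y, out_x, batch) column-major; columns enumerate
# (k_y, k_x, channel). Entry = linear index into the padded array.
# Memoized per shape: training loops hit few distinct shapes.
im2col_index <- function(H, W, C, N, k) {
  key <- paste(H, W, C, N, k, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- im2col_index_build(H, W, C, N, k)
  if (length(.im2col_cache) < 64) .im2col_cache[[key]] <- val
  val
}

im2col_index_build <- function(H, W, C, N, k) {
  oh <- H - k + 1L; ow <- W - k + 1L
  base_y <- rep(seq_len(oh), times = ow)
  base_x <- rep(seq_len(ow), each = oh)
  rowpart <- rep(base_y + (base_x - 1L) * H, times = N) +
    rep((seq_len(N) - 1L) * H * W * C, each = oh * ow)
  ky <- rep(seq_len(k), times = k * C)
  kx <- rep(rep(seq_len(k), each = k), times = C)
  coff <- rep((seq_len(C) - 1L) * H * W, each = k * k)
  colpart <- (ky - 1L) + (kx - 1L) * H + coff
  list(idx = outer(rowpart, colpart, "+"), oh = oh, ow = ow)
}

pad_same <- function(x, k) {
  p <- (k - 1L) %/% 2L
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

conv_layer_forward <- function(x, W, b, k, padding, activation,
                               want_cache = FALSE) {
  if (padding == "same") x <- pad_same(x, k)
  d <- dim(x)
  ii <- im2col_index(d[1], d[2], d[3], d[4], k)
  P <- matrix(x[as.vector(ii$idx)], nrow(ii$idx), ncol(ii$idx))
  z <- P %*% W + matrix(b, nrow(P), length(b), byrow = TRUE)
  a <- activate(z, activation)
  cout <- length(b)
  out <- aperm(array(a, c(ii$oh, ii$ow, d[4], cout)), c(1, 2, 4, 3))
  if (!want_cache) return(out)
  list(out = out, P = P, z = z, idx = ii$idx, padded_dim = d)
}

conv_layer_backward <- function(dout, cache, W, k, padding, activation,
                                input_dim) {
  cout <- ncol(W)
  dmat <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = cout)
  dz <- dmat * activate_grad(cache$z, activation)
  dW <- crossprod(cache$P, dz)
  db <- colSums(dz)
  dP <- tcrossprod(dz, W)
  dxp <- numeric(prod(cache$padded_dim))
  for (j in seq_len(ncol(cache$idx))) {
    ii <- cache$idx[, j]
    dxp[ii] <- dxp[ii] + dP[, j]
  }
  dxp <- array(dxp, dim = cache$padded_dim)
  if (padding == "same") {
    p <- (k - 1L) %/% 2L
    if (p > 0) {
      dxp <- dxp[p + seq_len(input_dim[1]), p + seq_len(input_dim[2]), , ,
                 drop = FALSE]
    }
  }
  list(dx = dxp, dW = dW, db = db)
}

#' Convolutional layer forward pass
#'
#' Computes each output matrix as the activated sum over input channels of
#' the input cross-correlated with its kernel, plus a per-output bias:
#' `A_j = f(sum_i I_i * K_{i,j} + B_j)` with "valid" spatial support.
#'
#' @param inputs a single matrix, a list of N input matrices, or an
#'   h x w x N array.
#' @param kernels a k x k matrix (single input/output), a nested list
#'   `kernels[[i]][[j]]`, or a k x k x N x M array; one kernel per
#'   (input i, output j) pair.
#' @param biases numeric vector, one bias per output matrix.
#' @param activation `"relu"`, `"linear"` or `"sigmoid"`.
#' @return list of M output matrices (a single matrix if M = 1).
#' @export
conv_forward <- function(inputs, kernels, biases = 0, activation = "linear") {
  if (is.matrix(inputs)) inputs <- list(inputs)
  if (is.array(inputs) && length(dim(inputs)) == 3)
    inputs <- lapply(seq_len(dim(inputs)[3]), function(i) inputs[, , i])
  N <- length(inputs)
  if (is.matrix(kernels)) kernels <- list(list(kernels))
  if (is.array(kernels) && length(dim(kernels)) == 4) {
    ka <- kernels
    kernels <- lapply(seq_len(dim(ka)[3]), function(i)
      lapply(seq_len(dim(ka)[4]), function(j) ka[, , i, j]))
  }
  if (length(kernels) != N)
    stop("dimension error: need one kernel row per input matrix")
  M <- length(kernels[[1]])
  if (length(biases) == 1) biases <- rep(biases, M)
  if (length(biases) != M)
    stop("dimension error: one bias per output matrix")
  k <- nrow(kernels[[1]][[1]])
  hw <- dim(inputs[[1]])
  if (any(vapply(inputs, function(m) !all(dim(m) == hw), logical(1))))
    stop("dimension error: input matrices must share a shape")
  if (k > min(hw)) stop("dimension error: kernel larger than input")
  x <- array(unlist(inputs), dim = c(hw[1], hw[2], N, 1))
  W <- matrix(0, k * k * N, M)
  for (i in seq_len(N)) for (j in seq_len(M)) {
    kr <- kernels[[i]][[j]]
    if (!all(dim(kr) == c(k, k))) stop("dimension error: ragged kernels")
    W[(i - 1) * k * k + seq_len(k * k), j] <- as.numeric(kr)
  }
  out <- conv_layer_forward(x, W, biases, k, "valid", activation)
  res <- lapply(seq_len(M), function(j)
    matrix(out[, , j, 1], dim(out)[1], dim(out)[2]))
  if (M == 1) res[[1]] else res
}

#' 2x2 max pooling
#'
#' Each output element is the maximum of a disjoint 2x2 block; spatial
#' dimensions are halved (odd trailing rows/columns are dropped).
#'
#' @param m a matrix or an (h, w, c, n) array.
#' @return pooled object of the same kind.
#' @export
maxpool2x2 <- function(m) {
  if (is.matrix(m)) {
    x <- array(m, dim = c(dim(m), 1, 1))
    out <- maxpool_forward(x)$out
    return(matrix(out, dim(out)[1], dim(out)[2]))
  }
  maxpool_forward(m)$out
}

pool_views <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  ri <- seq_len(2L * h2); ci <- seq_len(2L * w2)
  xc <- x[ri, ci, , , drop = FALSE]
  odd_r <- seq(1L, 2L * h2, by = 2L); ev_r <- odd_r + 1L
  odd_c <- seq(1L, 2L * w2, by = 2L); ev_c <- odd_c + 1L
  list(
    v = list(xc[odd_r, odd_c, , , drop = FALSE],
             xc[ev_r, odd_c, , , drop = FALSE],
             xc[odd_r, ev_c, , , drop = FALSE],
             xc[ev_r, ev_c, , , drop = FALSE]),
    h2 = h2, w2 = w2, odd_r = odd_r, ev_r = ev_r, odd_c = odd_c, ev_c = ev_c
  )
}

maxpool_forward <- function(x) {
  pv <- pool_views(x)
  out <- pmax(pv$v[[1]], pv$v[[2]], pv$v[[3]], pv$v[[4]])
  list(out = out, views = pv, input_dim = dim(x))
}

maxpool_backward <- function(dout, cache) {
  pv <- cache$views
  out <- pmax(pv$v[[1]], pv$v[[2]], pv$v[[3]], pv$v[[4]])
  dx <- array(0, dim = cache$input_dim)
  taken <- array(FALSE, dim = dim(out))
  rows <- list(pv$odd_r, pv$ev_r, pv$odd_r, pv$ev_r)
  cols <- list(pv$odd_c, pv$odd_c, pv$ev_c, pv$ev_c)
  for (q in 1:4) {
    hit <- (pv$v[[q]] == out) & !taken     # ties routed to the first view
    taken <- taken | hit
    g <- dout * hit
    dx[rows[[q]], cols[[q]], , ] <-
      dx[rows[[q]], cols[[q]], , , drop = FALSE] + g
  }
  dx
}

upsample_forward <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  list(out = x[ri, ci, , , drop = FALSE], input_dim = d)
}

upsample_backward <- function(dout, cache) {
  d <- cache$input_dim
  odd_r <- seq(1L, 2L * d[1], by = 2L); odd_c <- seq(1L, 2L * d[2], by = 2L)
  dout[odd_r, odd_c, , , drop = FALSE] +
    dout[odd_r + 1L, odd_c, , , drop = FALSE] +
    dout[odd_r, odd_c + 1L, , , drop = FALSE] +
    dout[odd_r + 1L, odd_c + 1L, , , drop = FALSE]
}

flatten_forward <- function(x) {
  d <- dim(x)
  list(out = t(matrix(x, prod(d[1:3]), d[4])), input_dim = d)
}

flatten_backward <- function(dout, cache) {
  array(t(dout), dim = cache$input_dim)
}

dense_forward <- function(x, W, b, activation, want_cache = FALSE) {
  z <- x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE)
  a <- activate(z, activation)
  if (!want_cache) return(a)
  list(out = a, x = x, z = z)
}

dense_backward <- function(dout, cache, W, activation) {
  dz <- dout * activate_grad(cache$z, activation)
  list(dx = tcrossprod(dz, W), dW = crossprod(cache$x, dz), db = colSums(dz))
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim = dim(x) %||% length(x))
  list(out = x * mask / (1 - rate), mask = mask, rate = rate)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) return(dout)
  dout * cache$mask / (1 - cache$rate)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
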