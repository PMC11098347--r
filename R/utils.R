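# Internal helpers shared across modules: argument checking, seeded RNG
# scoping, reflect padding, sliding-window gathers and small-kernel
# convolution built on gather + matrix multiply.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(msg) {
  rlang::abort(msg, class = "lungsev_input_error")
}

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L) {
    abort_input(sprintf("`%s` must be a non-empty numeric matrix.", arg))
  }
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  check_image(mask, arg)
  if (!all(mask %in% c(0, 1))) {
    abort_input(sprintf("`%s` must be a binary {0,1} matrix.", arg))
  }
  invisible(mask)
}

check_same_shape <- function(a, b, args = c("a", "b")) {
  if (!identical(dim(a), dim(b))) {
    abort_input(sprintf("`%s` and `%s` must have identical dimensions.",
                        args[1], args[2]))
  }
  invisible(NULL)
}

check_odd_window <- function(window, min = 3L, arg = "window") {
  if (length(window) != 1L || is.na(window) || window < min || window %% 2L == 0L) {
    abort_input(sprintf("`%s` must be an odd integer >= %d.", arg, min))
  }
  invisible(as.integer(window))
}

#' @noRd
clip01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-item child seed derived from a master seed (counter-based
# LCG step, kept inside the 32-bit signed range).
child_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

# Reflect (mirror, no edge repeat avoided -- base "symmetric" reflection that
# repeats the border row once) padding by `p` pixels on every side.
pad_reflect <- function(img, p) {
  h <- nrow(img); w <- ncol(img)
  if (p >= h || p >= w) abort_input("padding exceeds image size")
  ri <- c(p:1, 1:h, h:(h - p + 1))
  ci <- c(p:1, 1:w, w:(w - p + 1))
  img[ri, ci, drop = FALSE]
}

pad_zero <- function(img, p) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h + 2 * p, w + 2 * p)
  out[(p + 1):(p + h), (p + 1):(p + w)] <- img
  out
}

# Index matrix for gathering k x k neighborhoods from a padded image:
# row i of the result lists the padded linear indices of the window centered
# on the i-th pixel (column-major pixel order), columns ordered by kernel
# position (column-major over the k x k window).
window_index <- function(h, w, k) {
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p
  centers_r <- rep(seq_len(h), times = w) + p
  centers_c <- rep(seq_len(w), each = h) + p
  offs <- expand.grid(dr = -p:p, dc = -p:p)
  idx <- matrix(0L, h * w, k * k)
  for (o in seq_len(nrow(offs))) {
    idx[, o] <- (centers_c + offs$dc[o] - 1L) * hp + (centers_r + offs$dr[o])
  }
  idx
}

# Gather neighborhoods: returns an (h*w) x (k*k) matrix of window values.
gather_windows <- function(img, k, pad = c("reflect", "zero")) {
  pad <- match.arg(pad)
  p <- (k - 1L) %/% 2L
  padded <- if (pad == "reflect") pad_reflect(img, p) else pad_zero(img, p)
  idx <- window_index(nrow(img), ncol(img), k)
  matrix(padded[idx], nrow = nrow(idx), ncol = ncol(idx))
}

# Exact row-wise medians of a matrix with an odd number of columns, via a
# single radix sort over (row, value) pairs.
row_medians <- function(X) {
  n <- nrow(X); k <- ncol(X)
  stopifnot(k %% 2L == 1L)
  ord <- order(rep(seq_len(n), times = k), X)
  sorted <- matrix(X[ord], nrow = n, ncol = k, byrow = TRUE)
  sorted[, (k + 1L) %/% 2L]
}

# 'Same'-size 2-D convolution (correlation with the kernel as printed) of an
# image with one or more k x k kernels. `kernels`: k x k matrix or a
# (k*k) x m matrix of vectorized kernels. Returns (h*w) x m response matrix.
conv2_same <- function(img, kernels, pad = "reflect") {
  if (is.matrix(kernels) && nrow(kernels) == ncol(kernels) &&
      nrow(kernels) %% 2L == 1L && is.null(attr(kernels, "stacked"))) {
    k <- nrow(kernels)
    kernels <- matrix(as.vector(kernels), ncol = 1)
  } else {
    k <- as.integer(sqrt(nrow(kernels)))
  }
  X <- gather_windows(img, k, pad)
  X %*% kernels
}

# Nearest-neighbour / bilinear resize of a matrix to h x w.
resize_image <- function(img, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h0 <- nrow(img); w0 <- ncol(img)
  if (h0 == h && w0 == w) return(img)
  if (method == "nearest") {
    ri <- pmin(h0, pmax(1L, as.integer(floor((seq_len(h) - 0.5) * h0 / h) + 1L)))
    ci <- pmin(w0, pmax(1L, as.integer(floor((seq_len(w) - 0.5) * w0 / w) + 1L)))
    return(img[ri, ci, drop = FALSE])
  }
  # bilinear on pixel centers
  rf <- (seq_len(h) - 0.5) * h0 / h + 0.5
  cf <- (seq_len(w) - 0.5) * w0 / w + 0.5
  r0 <- pmin(h0 - 1L, pmax(1L, floor(rf))); r1 <- r0 + 1L
  c0 <- pmin(w0 - 1L, pmax(1L, floor(cf))); c1 <- c0 + 1L
  wr <- pmin(1, pmax(0, rf - r0)); wc <- pmin(1, pmax(0, cf - c0))
  a <- img[r0, c0, drop = FALSE] * ((1 - wr) %o% (1 - wc)) +
    img[r1, c0, drop = FALSE] * (wr %o% (1 - wc)) +
    img[r0, c1, drop = FALSE] * ((1 - wr) %o% wc) +
    img[r1, c1, drop = FALSE] * (wr %o% wc)
  a
}

# One-hot encode integer labels 0..(k-1) into an n x k matrix.
one_hot <- function(labels, k = 4L) {
  n <- length(labels)
  out <- matrix(0, n, k)
  out[cbind(seq_len(n), labels + 1L)] <- 1
  out
}
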