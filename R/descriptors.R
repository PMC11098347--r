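# Handcrafted texture and shape descriptors computed on the segmented
# lung image: modified local directional number patterns (MLDN) from an
# 8-direction compass of Gaussian-derivative masks, median-robust local
# binary patterns with entropy, and shape features of the binary mask.

#' Gaussian compass-mask kernel
#'
#' `g(p,q) = 1/(2*pi*sigma^2) * exp(-(p^2+q^2)/(2*sigma^2))` evaluated on a
#' centered integer grid.
#'
#' @param sigma Gaussian bell width (> 0).
#' @param size Odd kernel side.
#' @return `size x size` numeric matrix, symmetric under `(p,q) -> (-p,-q)`.
#' @export
gaussian_mask <- function(sigma = 0.5, size = 7L) {
  if (sigma <= 0) abort_input("`sigma` must be > 0.")
  size <- check_odd_window(size, min = 1L, arg = "size")
  h <- (size - 1L) %/% 2L
  p <- matrix(-h:h, size, size)          # row offset
  q <- matrix(-h:h, size, size, byrow = TRUE) # column offset
  exp(-(p^2 + q^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
}

#' Asymmetric (logistic-weighted) Gaussian mask
#'
#' The Gaussian kernel of [gaussian_mask()] multiplied by the logistic
#' factor `1 / (1 + exp(-(p+q)/2))`, which amplifies the half-plane
#' `p + q > 0` relative to its mirror and so breaks the central symmetry
#' of the plain Gaussian. With `logistic = FALSE` the factor is dropped
#' and the plain Gaussian is returned.
#'
#' @inheritParams gaussian_mask
#' @param logistic Apply the asymmetric logistic factor?
#' @return `size x size` numeric matrix.
#' @export
improved_gaussian_mask <- function(sigma = 0.5, size = 7L, logistic = TRUE) {
  g <- gaussian_mask(sigma, size)
  if (!logistic) return(g)
  h <- (size - 1L) %/% 2L
  p <- matrix(-h:h, size, size)
  q <- matrix(-h:h, size, size, byrow = TRUE)
  g * stats::plogis((p + q) / 2)
}

# Exact 45-degree kernel rotation: every concentric square ring of a
# (2r+1)-cell-wide odd kernel holds 8r cells; a 45-degree turn is a cyclic
# shift of each ring by r cells. Eight applications are the identity,
# bit-exactly -- this is how the classic Kirsch compass is rotated.
ring_coords <- function(size, r) {
  c0 <- (size + 1L) %/% 2L
  top <- cbind(c0 - r, (c0 - r):(c0 + r))
  right <- cbind((c0 - r + 1L):(c0 + r), c0 + r)
  bottom <- cbind(c0 + r, (c0 + r - 1L):(c0 - r))
  left <- cbind((c0 + r - 1L):(c0 - r + 1L), c0 - r)
  rbind(top, right, bottom, left)
}

#' Rotate an odd square kernel by multiples of 45 degrees
#'
#' @param kernel Odd square numeric matrix.
#' @param times Number of 45-degree steps.
#' @return Rotated kernel; `times = 8` returns the input exactly.
#' @export
rotate_kernel_45 <- function(kernel, times = 1L) {
  size <- nrow(kernel)
  check_odd_window(size, min = 1L, arg = "kernel size")
  out <- kernel
  for (r in seq_len((size - 1L) %/% 2L)) {
    rc <- ring_coords(size, r)
    n <- nrow(rc)
    shift <- (times * r) %% n
    out[rc[(seq_len(n) - 1L + shift) %% n + 1L, , drop = FALSE]] <- kernel[rc]
  }
  out
}

kirsch_masks <- function() {
  base <- matrix(c(-3, -3, -3, -3, 0, -3, 5, 5, 5), 3, 3) # east
  lapply(0:7, function(i) rotate_kernel_45(base, i))
}

# Convolve two odd kernels and crop the full result back to `size`.
kernel_convolve <- function(a, b) {
  size <- nrow(a)
  full <- matrix(0, 2 * size - 1, 2 * size - 1)
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      full[i:(i + size - 1), j:(j + size - 1)] <-
        full[i:(i + size - 1), j:(j + size - 1)] + a[i, j] * b
    }
  }
  h <- (size - 1L) %/% 2L
  ctr <- size
  full[(ctr - h):(ctr + h), (ctr - h):(ctr + h)]
}

# 3x3 median smoothing of a kernel (zero padding).
kernel_median3 <- function(k) {
  X <- gather_windows(k, 3L, pad = "zero")
  matrix(row_medians(X), nrow(k), ncol(k))
}

#' Eight-direction compass masks
#'
#' Builds the kernel bank driving the directional-number code. The
#' `"modified_gaussian"` family starts from an offset derivative-of-Gaussian
#' (`-(p+k)/sigma^2 * g(p+k, q)`) convolved with the asymmetric Gaussian of
#' [improved_gaussian_mask()], median-smoothed (3x3) for noise robustness,
#' renormalized to zero sum, and rotated through the eight compass
#' directions by exact 45-degree ring shifts. The `"kirsch"` family returns
#' the eight standard 3x3 Kirsch operators.
#'
#' @param family `"modified_gaussian"` or `"kirsch"`.
#' @param sigma Gaussian bell width.
#' @param offset_k Offset of the Gaussian derivative from the kernel
#'   center, in pixels.
#' @param size Odd kernel side for the Gaussian family.
#' @param logistic Apply the asymmetric logistic factor (see
#'   [improved_gaussian_mask()]).
#' @return List of 8 kernels ordered by rotation angle (0, 45, ..., 315
#'   degrees).
#' @export
compass_masks <- function(family = c("modified_gaussian", "kirsch"),
                          sigma = 0.5, offset_k = 2L, size = 7L,
                          logistic = TRUE) {
  family <- match.arg(family)
  if (family == "kirsch") return(kirsch_masks())
  size <- check_odd_window(size, min = 3L, arg = "size")
  h <- (size - 1L) %/% 2L
  p <- matrix(-h:h, size, size)
  q <- matrix(-h:h, size, size, byrow = TRUE)
  dgauss <- -(p + offset_k) / sigma^2 *
    exp(-((p + offset_k)^2 + q^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  base <- kernel_median3(kernel_convolve(dgauss, improved_gaussian_mask(sigma, size, logistic)))
  base <- base - mean(base) # zero DC response
  lapply(0:7, function(i) rotate_kernel_45(base, i))
}

# Map (i_max, i_min) pairs (0-based) to the 56 valid directional codes;
# tied/constant responses collapse to code 0.
ldn_code_index <- function(i_max, i_min) {
  code <- 7L * i_max + i_min - as.integer(i_min > i_max)
  code[i_max == i_min] <- 0L
  code
}

#' Modified local directional number descriptor
#'
#' Convolves the image with the eight compass masks, codes every pixel by
#' the pair (direction of maximum response, direction of minimum response)
#' -- 56 valid codes, ties broken toward the lowest direction index and
#' constant-response pixels coded 0 -- and pools the codes into a grid of
#' per-region 56-bin histograms, each L1-normalized and concatenated.
#'
#' @param img Numeric image matrix.
#' @param mask Optional binary mask; when supplied the descriptor is
#'   computed on the image cropped to the mask's bounding box. The crop is
#'   not zeroed outside the mask: blanking would imprint a strong
#'   artificial edge along the mask boundary whose directional codes
#'   dominate the histograms and drown the texture inside the region.
#' @param family Compass family: `"both"` (default; the descriptor pairs
#'   the Kirsch and derivative-Gaussian compasses and concatenates their
#'   code histograms), `"kirsch"`, or `"modified_gaussian"`.
#' @param sigma,offset_k,mask_size,logistic Gaussian compass-mask
#'   parameters (see [compass_masks()]).
#' @param grid Histogram pooling grid (`grid x grid` regions).
#' @return Named numeric vector: `56 * grid^2` per mask family (`mldn_*`).
#' @export
mldn_descriptor <- function(img, mask = NULL,
                            family = c("both", "modified_gaussian",
                                       "kirsch"),
                            sigma = 0.5, offset_k = 2L, mask_size = 7L,
                            grid = 4L, logistic = TRUE) {
  family <- match.arg(family)
  check_image(img)
  img <- crop_to_mask(img, mask, zero_outside = FALSE)
  if (nrow(img) < mask_size || ncol(img) < mask_size) {
    abort_input("image (or mask bounding box) smaller than the compass mask.")
  }
  families <- if (family == "both") c("kirsch", "modified_gaussian") else family
  out <- numeric(0)
  for (fam in families) {
    masks <- compass_masks(fam, sigma, offset_k, mask_size, logistic)
    codes <- ldn_code_map(img, masks)
    h <- pooled_histograms(codes, bins = 56L, grid = grid,
                           prefix = paste0("mldn_", substr(fam, 1, 1)))
    out <- c(out, h)
  }
  out
}

# Per-pixel directional-number codes for one compass bank.
ldn_code_map <- function(img, masks) {
  ksize <- nrow(masks[[1]])
  bank <- vapply(masks, as.vector, numeric(ksize * ksize))
  resp <- conv2_same(img, bank, pad = "reflect")
  i_max <- max.col(resp, ties.method = "first") - 1L
  i_min <- max.col(-resp, ties.method = "first") - 1L
  # constant-response pixels (all eight responses equal up to fp noise)
  # carry no direction and are coded 0
  flat <- (resp[cbind(seq_len(nrow(resp)), i_max + 1L)] -
             resp[cbind(seq_len(nrow(resp)), i_min + 1L)]) < 1e-12
  i_min[flat] <- i_max[flat]
  matrix(ldn_code_index(i_max, i_min), nrow(img), ncol(img))
}

# Split code map into grid x grid regions and concatenate L1-normalized
# histograms.
pooled_histograms <- function(codes, bins, grid, prefix) {
  rs <- split_indices(nrow(codes), grid)
  cs <- split_indices(ncol(codes), grid)
  out <- numeric(0)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      cell <- codes[rs[[i]], cs[[j]]]
      h <- tabulate(cell + 1L, nbins = bins)
      out <- c(out, h / max(sum(h), 1L))
    }
  }
  names(out) <- sprintf("%s_%04d", prefix, seq_along(out) - 1L)
  out
}

split_indices <- function(n, g) {
  bounds <- floor(seq(0, n, length.out = g + 1))
  lapply(seq_len(g), function(i) (bounds[i] + 1):bounds[i + 1])
}

crop_to_mask <- function(img, mask, zero_outside = TRUE) {
  if (is.null(mask)) return(img)
  check_mask(mask)
  check_same_shape(img, mask, c("img", "mask"))
  if (sum(mask) == 0) return(img)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  if (zero_outside) img <- img * mask
  img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
}

#' Median-robust local binary pattern code map
#'
#' The image is first median-filtered (robustness prefilter), then globally
#' mean-centered (a no-op for the sign comparisons, retained as part of the
#' descriptor definition), and finally coded with the LBP operator: for
#' each interior pixel, `code = sum_n s(z_n - z_c) * 2^n` over `neighbors`
#' points sampled on a circle of the given radius (bilinear interpolation
#' at non-integer positions), with `s(z) = 1` iff `z >= 0`.
#'
#' @param img Numeric image matrix.
#' @param neighbors Number of circle samples (4, 8 or 16).
#' @param radius Circle radius in pixels (>= 1).
#' @param median_window Odd side of the median prefilter.
#' @return Integer matrix of codes in `[0, 2^neighbors - 1]` for the
#'   interior pixels (a margin of `ceiling(radius)` is dropped), with
#'   attribute `"neighbors"`.
#' @examples
#' mrelbp_map(matrix(0.5, 8, 8))[1, 1]  # constant image codes to 255
#' @export
mrelbp_map <- function(img, neighbors = 8L, radius = 1L, median_window = 3L) {
  check_image(img)
  if (!neighbors %in% c(4L, 8L, 16L)) abort_input("`neighbors` must be 4, 8 or 16.")
  if (radius < 1) abort_input("`radius` must be >= 1.")
  m <- as.integer(ceiling(radius))
  if (nrow(img) <= 2 * m || ncol(img) <= 2 * m) {
    abort_input("`radius` too large for the image.")
  }
  median_window <- check_odd_window(median_window)
  z <- matrix(row_medians(gather_windows(img, median_window, "reflect")),
              nrow(img), ncol(img))
  z <- z - mean(z)
  h <- nrow(z); w <- ncol(z)
  rows <- (m + 1):(h - m); cols <- (m + 1):(w - m)
  zc <- z[rows, cols]
  code <- matrix(0L, length(rows), length(cols))
  for (n in 0:(neighbors - 1L)) {
    th <- 2 * pi * n / neighbors
    dr <- -radius * sin(th); dc <- radius * cos(th)
    dr <- ifelse(abs(dr - round(dr)) < 1e-9, round(dr), dr)
    dc <- ifelse(abs(dc - round(dc)) < 1e-9, round(dc), dc)
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    zn <- (1 - fr) * (1 - fc) * z[rows + r0, cols + c0]
    if (fr > 0) zn <- zn + fr * (1 - fc) * z[rows + r0 + 1, cols + c0]
    if (fc > 0) zn <- zn + (1 - fr) * fc * z[rows + r0, cols + c0 + 1]
    if (fr > 0 && fc > 0) zn <- zn + fr * fc * z[rows + r0 + 1, cols + c0 + 1]
    code <- code + bitwAnd(1L, as.integer(zn - zc >= 0)) * 2L^n
  }
  structure(code, neighbors = neighbors)
}

#' Histogram of local binary pattern codes
#'
#' @param code_map Integer code matrix (as from [mrelbp_map()]).
#' @param bins Number of code bins (`2^neighbors`).
#' @return Tibble with columns `code`, `count`, `prob` (L1-normalized).
#' @export
lbp_histogram <- function(code_map, bins = 256L) {
  codes <- as.integer(code_map)
  if (any(codes < 0) || any(codes >= bins)) {
    rlang::abort("LBP code outside [0, bins): internal coding error.",
                 class = "lungsev_internal_error")
  }
  counts <- tabulate(codes + 1L, nbins = bins)
  tibble::tibble(code = 0:(bins - 1L), count = counts,
                 prob = counts / sum(counts))
}

#' Shannon entropy of a probability vector
#'
#' `H = sum_i p_i * log2(1/p_i)`, in bits; zero bins contribute 0. Bounded
#' by `log2(length(p))`, with equality iff uniform.
#'
#' @param p Nonnegative probabilities summing to 1 (within 1e-6).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    abort_input("`p` must be nonnegative and sum to 1.")
  }
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' MRELBP histogram + entropy feature vector
#'
#' Concatenates the L1-normalized MRELBP code histogram with its scalar
#' Shannon entropy: length `2^neighbors + 1`.
#'
#' @inheritParams mrelbp_map
#' @param mask Optional binary mask (bounding-box crop, as for
#'   [mldn_descriptor()]).
#' @return Named numeric vector (`elbp_*`, `elbp_entropy`).
#' @export
elbp_feature <- function(img, mask = NULL, neighbors = 8L, radius = 1L,
                         median_window = 3L) {
  img <- crop_to_mask(img, mask)
  cm <- mrelbp_map(img, neighbors, radius, median_window)
  h <- lbp_histogram(cm, bins = 2L^neighbors)
  out <- c(h$prob, shannon_entropy(h$prob))
  names(out) <- c(sprintf("elbp_%03d", h$code), "elbp_entropy")
  out
}

#' Shape features of a binary mask
#'
#' Area (pixel count), perimeter (count of mask pixels with at least one
#' 4-connected background neighbor, image border counting as background),
#' convex hull area and perimeter computed on pixel-center coordinates
#' (shoelace formula), and solidity `area / max(hull_area, 1)`.
#'
#' @param mask Binary matrix; an empty mask yields an all-zero report.
#' @return One-row tibble: `area`, `perimeter`, `hull_area`,
#'   `hull_perimeter`, `solidity`.
#' @examples
#' m <- matrix(0, 12, 12); m[2:11, 2:11] <- 1
#' shape_features(m)  # area 100, perimeter 36, hull_area 81
#' @export
shape_features <- function(mask) {
  check_mask(mask)
  area <- sum(mask)
  if (area == 0) {
    return(tibble::tibble(area = 0, perimeter = 0, hull_area = 0,
                          hull_perimeter = 0, solidity = 0))
  }
  p <- pad_zero(mask, 1L)
  h <- nrow(mask); w <- ncol(mask)
  core <- p[2:(h + 1), 2:(w + 1)]
  nb_min <- pmin(p[1:h, 2:(w + 1)], p[3:(h + 2), 2:(w + 1)],
                 p[2:(h + 1), 1:w], p[2:(h + 1), 3:(w + 2)])
  perimeter <- sum(core == 1 & nb_min == 0)
  pts <- which(mask == 1, arr.ind = TRUE)
  xy <- cbind(x = pts[, "col"] - 1, y = pts[, "row"] - 1)
  hull_area <- 0; hull_perimeter <- 0
  hull <- unique(xy[grDevices::chull(xy), , drop = FALSE])
  if (nrow(hull) >= 2) {
    nxt <- c(2:nrow(hull), 1)
    hull_perimeter <- sum(sqrt(rowSums((hull - hull[nxt, , drop = FALSE])^2)))
    if (nrow(hull) >= 3) {
      hull_area <- abs(sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2])) / 2
    }
  }
  tibble::tibble(area = area, perimeter = perimeter, hull_area = hull_area,
                 hull_perimeter = hull_perimeter,
                 solidity = area / max(hull_area, 1))
}
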