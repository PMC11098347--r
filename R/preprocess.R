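#' Power spectral density of an image
#'
#' Squared magnitude of the 2-D discrete Fourier transform divided by the
#' pixel count. Equivalent (by the Wiener-Khinchin theorem) to the DFT of
#' the image's circular autocorrelation; the DC entry equals
#' `sum(img)^2 / length(img)`.
#'
#' @param img Numeric matrix.
#' @return Nonnegative matrix of the same dimensions.
#' @export
power_spectral_density <- function(img) {
  check_image(img)
  Mod(stats::fft(img))^2 / length(img)
}

#' Denoising quality report (PSNR, SNR and their product)
#'
#' Scores a restored image against its reference. Both images are rescaled
#' internally to the 8-bit range `[0,255]`. The report contains the mean
#' squared error, the 255-peak PSNR `10*log10(255^2/mse)`, an SNR built
#' from the harmonic mean of the restored image's positive pixel values
#' (`10*log10(H^2/(2*Var))`, with `Var` the mean squared deviation of those
#' values from `H`), and their product as a combined score. Identical
#' images give `psnr = Inf` (and so `combined = Inf`); an all-zero restored
#' image has no harmonic mean, is flagged degenerate, and reports `snr = 0`.
#'
#' @param original,restored Numeric matrices of identical shape.
#' @return A one-row tibble with columns `mse`, `psnr`, `snr`, `combined`,
#'   `degenerate`.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' image_quality(img, img)$psnr  # Inf
#' @export
image_quality <- function(original, restored) {
  check_image(original, "original"); check_image(restored, "restored")
  check_same_shape(original, restored, c("original", "restored"))
  to8 <- function(x) if (max(x) <= 1) x * 255 else x
  e0 <- to8(original); e1 <- to8(restored)
  mse <- mean((e1 - e0)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
  pos <- e1[e1 > 0]
  degenerate <- length(pos) == 0L
  if (degenerate) {
    snr <- 0
  } else {
    hmean <- length(pos) / sum(1 / pos)
    v <- mean((pos - hmean)^2)
    snr <- if (v == 0) Inf else 10 * log10(hmean^2 / (2 * v))
  }
  combined <- if (is.infinite(psnr)) Inf else psnr * snr
  tibble::tibble(mse = mse, psnr = psnr, snr = snr,
                 combined = combined, degenerate = degenerate)
}

#' Sliding-window local statistics
#'
#' Local mean, population variance (divisor = window area) and exact median
#' over an odd square window centered on each pixel, with reflect padding
#' at the borders.
#'
#' @param img Numeric matrix at least `window` pixels in each dimension.
#' @param window Odd window side, >= 3.
#' @return An object of class `local_stats`: list of matrices `mean_map`,
#'   `var_map`, `median_map` matching `img`.
#' @export
local_stats <- function(img, window = 5L) {
  check_image(img)
  window <- check_odd_window(window)
  if (nrow(img) < window || ncol(img) < window) {
    abort_input("`window` larger than the image.")
  }
  X <- gather_windows(img, window, pad = "reflect")
  mu <- rowMeans(X)
  v <- rowMeans(X^2) - mu^2
  v[v < 0] <- 0 # guard fp cancellation
  med <- row_medians(X)
  d <- dim(img)
  structure(
    list(mean_map = matrix(mu, d[1], d[2]),
         var_map = matrix(v, d[1], d[2]),
         median_map = matrix(med, d[1], d[2]),
         window = window),
    class = "local_stats"
  )
}

#' Improved Wiener filter
#'
#' Adaptive median-anchored Wiener denoising. For every pixel the local
#' median `Med`, mean and variance `sigma2` over an odd window are computed
#' (reflect padding), the noise variance `V2` is subtracted from the local
#' variance (clamped at zero), and the pixel is pulled toward the local
#' median by the excess-variance ratio `r = max(0, sigma2 - V2) /
#' max(sigma2, epsilon)`:
#' \itemize{
#'   \item variant `"linear"` (pipeline default):
#'     `S = Med + r * (Img - Med)`;
#'   \item variant `"literal"`: `S = tanh(Med + r * (Img - Med) + 1)`,
#'     the update rule in its printed compressive form.
#' }
#' The output is clipped to `[0,1]`. With `V2 = 0` the linear variant is
#' the identity; with `V2 >= max(sigma2)` it is the local median filter.
#'
#' @param img Numeric matrix with intensities in `[0,1]`.
#' @param window Odd window side (default 5).
#' @param noise_variance Noise variance `V2` in squared intensity units, or
#'   `"auto"` to estimate it as the mean of the local variance map (the
#'   classical Lee-filter estimator).
#' @param variant `"linear"` or `"literal"`.
#' @param epsilon Small positive stabilizer for the variance ratio.
#' @return Filtered image matrix in `[0,1]`, with the estimated noise
#'   variance attached as attribute `"noise_variance"`.
#' @examples
#' img <- matrix(runif(256), 16, 16)
#' identical_out <- improved_wiener(img, noise_variance = 0)
#' all.equal(identical_out, img, check.attributes = FALSE)
#' @export
improved_wiener <- function(img, window = 5L, noise_variance = "auto",
                            variant = c("linear", "literal"),
                            epsilon = 1e-8) {
  variant <- match.arg(variant)
  stats_ <- local_stats(img, window)
  v2 <- if (identical(noise_variance, "auto")) {
    mean(stats_$var_map)
  } else {
    if (!is.numeric(noise_variance) || noise_variance < 0) {
      abort_input("`noise_variance` must be \"auto\" or a nonnegative number.")
    }
    noise_variance
  }
  r <- pmax(0, stats_$var_map - v2) / pmax(stats_$var_map, epsilon)
  med <- stats_$median_map
  s <- med + r * (img - med)
  if (variant == "literal") s <- tanh(s + 1)
  out <- clip01(s)
  attr(out, "noise_variance") <- v2
  out
}
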