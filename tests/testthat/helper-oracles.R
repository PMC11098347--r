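# Shared brute-force oracles, written independently of the package
# internals they check.

# O(window^2) sliding-window statistics with symmetric (reflect) padding.
oracle_local_stats <- function(img, window) {
  h <- nrow(img); w <- ncol(img); p <- (window - 1) %/% 2
  ri <- c(p:1, 1:h, h:(h - p + 1)); ci <- c(p:1, 1:w, w:(w - p + 1))
  padded <- img[ri, ci]
  mean_map <- var_map <- med_map <- matrix(0, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      vals <- padded[i:(i + window - 1), j:(j + window - 1)]
      mean_map[i, j] <- mean(vals)
      var_map[i, j] <- mean((vals - mean(vals))^2)
      med_map[i, j] <- median(vals)
    }
  }
  list(mean_map = mean_map, var_map = var_map, median_map = med_map)
}

# Per-pixel LBP with integer-rounded / bilinear circle sampling, written
# as explicit loops.
oracle_lbp <- function(z, neighbors, radius) {
  h <- nrow(z); w <- ncol(z); m <- ceiling(radius)
  out <- matrix(0L, h - 2 * m, w - 2 * m)
  for (i in (m + 1):(h - m)) {
    for (j in (m + 1):(w - m)) {
      code <- 0
      for (n in 0:(neighbors - 1)) {
        th <- 2 * pi * n / neighbors
        dr <- -radius * sin(th); dc <- radius * cos(th)
        if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
        if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
        r0 <- floor(dr); c0 <- floor(dc); fr <- dr - r0; fc <- dc - c0
        zn <- (1 - fr) * (1 - fc) * z[i + r0, j + c0]
        if (fr > 0) zn <- zn + fr * (1 - fc) * z[i + r0 + 1, j + c0]
        if (fc > 0) zn <- zn + (1 - fr) * fc * z[i + r0, j + c0 + 1]
        if (fr > 0 && fc > 0) zn <- zn + fr * fc * z[i + r0 + 1, j + c0 + 1]
        if (zn - z[i, j] >= 0) code <- code + 2^n
      }
      out[i - m, j - m] <- code
    }
  }
  out
}

# Two-loop softmax attention.
oracle_attention <- function(Q, K, V) {
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(Q))
    a <- exp(s - max(s)); a <- a / sum(a)
    out[i, ] <- colSums(a * V)
  }
  out
}

# Independent metric formulas, arranged differently from the package's.
oracle_metrics <- function(tp, tn, fp, fn) {
  prec <- tp / (tp + fp); sens <- tp / (tp + fn)
  list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = prec,
    sensitivity = sens,
    specificity = tn / (tn + fp),
    fnr = 1 - sens,
    fpr = 1 - tn / (tn + fp),
    f_measure = 2 * prec * sens / (prec + sens),
    mcc = (tp * tn - fp * fn) /
      sqrt(tp + fp) / sqrt(tp + fn) / sqrt(tn + fp) / sqrt(tn + fn),
    npv = tn / (tn + fn)
  )
}

random_mask <- function(h, w, p = 0.4) {
  matrix(as.numeric(runif(h * w) < p), h, w)
}
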