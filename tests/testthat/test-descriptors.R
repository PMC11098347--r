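test_that("Gaussian masks match the closed form and its symmetry", {
  g <- gaussian_mask(sigma = 0.5, size = 7)
  expect_equal(g[4, 4], 1 / (2 * pi * 0.25))
  expect_equal(g, g[7:1, 7:1]) # (p,q) -> (-p,-q)

  g1 <- gaussian_mask(sigma = 1, size = 9)
  expect_gte(sum(g1), 0.99)
  expect_lte(sum(g1), 1.0)
  expect_error(gaussian_mask(sigma = 1, size = 8),
               class = "lungsev_input_error")
})

test_that("the asymmetric Gaussian carries the logistic factor exactly", {
  ig <- improved_gaussian_mask(sigma = 0.5, size = 7)
  g <- gaussian_mask(sigma = 0.5, size = 7)
  expect_equal(ig[4, 4], g[4, 4] * 0.5) # sigmoid(0) = 1/2
  # ratio across mirrored diagonal positions: Gaussian part cancels
  expect_equal(ig[5, 5] / ig[3, 3], exp(1)) # sigmoid(1)/sigmoid(-1) = e
  expect_equal(improved_gaussian_mask(0.5, 7, logistic = FALSE), g)
})

test_that("compass masks: Kirsch table, zero DC, exact full-turn rotation", {
  k <- compass_masks("kirsch")
  expect_length(k, 8)
  expect_identical(k[[1]],
                   matrix(c(-3, -3, -3, -3, 0, -3, 5, 5, 5), 3, 3))
  expect_true(all(vapply(k, sum, numeric(1)) == 0))

  mg <- compass_masks("modified_gaussian")
  expect_length(mg, 8)
  for (m in mg) expect_lt(abs(sum(m)), 1e-6)
  expect_equal(rotate_kernel_45(mg[[1]], 8), mg[[1]], tolerance = 1e-3)
  expect_identical(rotate_kernel_45(k[[3]], 8), k[[3]])
  # the bank is the base mask under successive rotations
  expect_equal(mg[[4]], rotate_kernel_45(mg[[1]], 3))
})

test_that("directional-number codes behave on constant and edge images", {
  cimg <- matrix(0.5, 32, 32)
  v <- mldn_descriptor(cimg, grid = 2, family = "modified_gaussian")
  expect_length(v, 56 * 4)
  expect_length(mldn_descriptor(cimg, grid = 2, family = "both"), 2 * 56 * 4)
  hist1 <- v[1:56]
  expect_equal(unname(hist1[1]), 1) # every pixel coded 0 -> one-hot cells
  expect_equal(sum(hist1), 1)

  set.seed(2)
  img <- matrix(runif(32 * 32), 32, 32)
  v2 <- mldn_descriptor(img, grid = 4)
  cells <- matrix(v2, nrow = 56)
  expect_equal(colSums(cells), rep(1, 32), tolerance = 1e-9)
  expect_true(all(is.finite(v2)))
})

test_that("step-edge response directions match a brute-force convolution", {
  # vertical step edge: intensity jumps along columns
  img <- matrix(0, 24, 24); img[, 13:24] <- 1
  masks <- compass_masks("kirsch")
  # brute-force responses at interior pixels near the edge
  brute_code <- function(i, j) {
    resp <- vapply(masks, function(m) {
      s <- 0
      for (a in -1:1) for (b in -1:1) s <- s + m[a + 2, b + 2] * img[i + a, j + b]
      s
    }, numeric(1))
    c(which.max(resp), which.min(resp))
  }
  resp_pkg <- lungsev:::conv2_same(img, vapply(masks, as.vector, numeric(9)))
  for (i in c(8, 12, 16)) {
    for (j in c(12, 13)) {
      idx <- (j - 1) * 24 + i
      expect_equal(which.max(resp_pkg[idx, ]), brute_code(i, j)[1])
      expect_equal(which.min(resp_pkg[idx, ]), brute_code(i, j)[2])
    }
  }
})

test_that("binary-pattern maps match a per-pixel reimplementation", {
  expect_equal(unique(as.vector(mrelbp_map(matrix(0.5, 8, 8)))), 255)

  peak <- matrix(0, 5, 5); peak[3, 3] <- 1
  # median prefilter flattens a lone peak; use window 1 semantics via raw LBP:
  set.seed(9)
  img <- matrix(runif(100), 10, 10)
  got <- mrelbp_map(img, neighbors = 8, radius = 1, median_window = 3)
  z <- matrix(lungsev:::row_medians(lungsev:::gather_windows(img, 3L, "reflect")),
              10, 10)
  z <- z - mean(z)
  expect_equal(unclass(got), oracle_lbp(z, 8, 1), ignore_attr = TRUE)

  expect_error(mrelbp_map(img, neighbors = 5), class = "lungsev_input_error")
  expect_error(mrelbp_map(matrix(0, 2, 2), radius = 1),
               class = "lungsev_input_error")
})

test_that("a strictly dominant center codes to zero", {
  # radial bump: the median prefilter preserves the strict central maximum
  d <- as.matrix(stats::dist(expand.grid(1:11, 1:11)))
  img <- matrix(exp(-((row(matrix(0, 11, 11)) - 6)^2 +
                        (col(matrix(0, 11, 11)) - 6)^2) / 8), 11, 11)
  cm <- mrelbp_map(img, median_window = 3)
  expect_equal(cm[5, 5], 0) # output (5,5) is input (6,6), the peak
  # oracle agreement on the sign rule itself
  z <- matrix(0, 7, 7); z[4, 4] <- 5
  expect_equal(oracle_lbp(z - mean(z), 8, 1)[3, 3], 0)
})

test_that("histograms count codes, normalize, and add over partitions", {
  cm <- mrelbp_map(matrix(0.5, 10, 10))
  h <- lbp_histogram(cm)
  expect_equal(h$count[h$code == 255], length(cm))
  expect_equal(sum(h$prob), 1)

  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  cm <- mrelbp_map(img)
  h_all <- lbp_histogram(cm)
  h_a <- lbp_histogram(cm[, 1:9])
  h_b <- lbp_histogram(cm[, 10:18])
  expect_equal(h_a$count + h_b$count, h_all$count)
  expect_error(lbp_histogram(matrix(300, 2, 2)),
               class = "lungsev_internal_error")
})

test_that("entropy matches anchor distributions and its bound", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(rep(1 / 8, 8)), 3)
  set.seed(5)
  for (i in 1:20) {
    p <- runif(16); p <- p / sum(p)
    expect_lte(shannon_entropy(p), log2(16) + 1e-9)
  }
  expect_equal(shannon_entropy(rep(1 / 16, 16)), log2(16))
  expect_error(shannon_entropy(c(0.7, 0.7)), class = "lungsev_input_error")
})

test_that("the histogram+entropy feature has the documented layout", {
  e <- elbp_feature(matrix(0.5, 12, 12))
  expect_length(e, 257)
  expect_equal(unname(e["elbp_255"]), 1)
  expect_equal(unname(e["elbp_entropy"]), 0)

  set.seed(8)
  noise <- matrix(runif(144), 12, 12)
  expect_gt(elbp_feature(noise)["elbp_entropy"],
            elbp_feature(matrix(0.5, 12, 12))["elbp_entropy"])
})

test_that("pattern codes are invariant to a constant intensity shift", {
  set.seed(13)
  img <- matrix(runif(576), 24, 24)
  shifted <- img + 0.21
  expect_identical(unclass(mrelbp_map(img)), unclass(mrelbp_map(shifted)))
  expect_equal(mldn_descriptor(img, grid = 2),
               mldn_descriptor(shifted, grid = 2), tolerance = 1e-9)
})

test_that("shape features are exact on a filled square", {
  m <- matrix(0, 12, 12); m[2:11, 2:11] <- 1
  sf <- shape_features(m)
  expect_equal(sf$area, 100)
  expect_equal(sf$perimeter, 36)
  expect_equal(sf$hull_area, 81)
  expect_equal(sf$hull_perimeter, 36)
  expect_equal(sf$solidity, 100 / 81)
})

test_that("shape features translate and scale as geometry dictates", {
  set.seed(21)
  m <- matrix(0, 40, 40); m[5:28, 6:32] <- 1; m[20:36, 4:20] <- 1
  sf <- shape_features(m)
  shifted <- matrix(0, 44, 44); shifted[3:42, 4:43] <- m
  expect_equal(shape_features(shifted), sf)

  up <- m[rep(1:40, each = 2), rep(1:40, each = 2)]
  sf2 <- shape_features(up)
  expect_gte(sf2$area / sf$area, 3.6)
  expect_lte(sf2$area / sf$area, 4.4)
  expect_gte(sf2$hull_area / sf$hull_area, 3.6)
  expect_lte(sf2$hull_area / sf$hull_area, 4.4)

  expect_equal(shape_features(matrix(0, 5, 5))$area, 0)
})
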