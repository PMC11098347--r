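test_that("backbones have the stated depth and seeded determinism", {
  vgg <- build_backbone("vgg16", seed = 30)
  expect_equal(n_conv_layers(vgg), 13)
  res <- build_backbone("resnet", seed = 30)
  expect_gte(n_conv_layers(res), 9) # stem + 4 blocks of 2 (+ projections)

  vgg2 <- build_backbone("vgg16", seed = 30)
  expect_equal(vgg$convs[[1]]$par, vgg2$convs[[1]]$par)
  expect_error(build_backbone("vgg16", width_multiplier = 0),
               class = "lungsev_input_error")
  expect_error(build_backbone("vgg16", feature_dim = 4),
               class = "lungsev_input_error")
})

test_that("zeroed residual branches make a block the identity", {
  res <- build_backbone("resnet", seed = 31)
  blk <- res$stages[[1]] # same in/out width: identity skip
  expect_null(blk$proj)
  for (l in list(blk$conv1, blk$conv2)) {
    l$par$W <- l$par$W * 0
    l$par$b <- l$par$b * 0
  }
  x <- matrix(abs(rnorm(16 * 16 * res$widths[1])), 16 * 16, res$widths[1])
  fm <- lungsev:::fmap(x, 16L, 16L, 1L)
  out <- lungsev:::resnet_block_forward(blk, fm)
  expect_equal(out$x, x) # post-ReLU input passes through unchanged
})

test_that("deep features are fixed-length, deterministic and class-sensitive", {
  res <- build_backbone("resnet", seed = 32)
  s0 <- generate_phantom(phantom_spec(0, 64, seed = 1))
  s1 <- generate_phantom(phantom_spec(1, 64, seed = 1))
  f0 <- extract_deep_features(res, s0$image)
  expect_length(f0, 32)
  expect_identical(f0, extract_deep_features(res, s0$image))
  expect_true(all(is.finite(f0)))

  # centroids of the two classes differ (non-degenerate embedding)
  f0s <- vapply(1:5, function(i) {
    extract_deep_features(res, generate_phantom(phantom_spec(0, 64,
                                                             seed = i))$image)
  }, numeric(32))
  f1s <- vapply(1:5, function(i) {
    extract_deep_features(res, generate_phantom(phantom_spec(1, 64,
                                                             seed = i))$image)
  }, numeric(32))
  c0 <- rowMeans(f0s); c1 <- rowMeans(f1s)
  cosdist <- 1 - sum(c0 * c1) / sqrt(sum(c0^2) * sum(c1^2))
  expect_gt(cosdist, 0)

  # extraction does not mutate the weights
  w_before <- res$stem$par$W
  invisible(extract_deep_features(res, s1$image))
  expect_identical(res$stem$par$W, w_before)
})

test_that("the assembled feature set records its block schema", {
  s <- generate_phantom(phantom_spec(2, 64, seed = 4))
  bbs <- list(res = build_backbone("resnet", seed = 1),
              vgg = build_backbone("vgg16", seed = 2))
  v <- extract_feature_set(s$image, s$lung_mask, bbs)
  schema <- attr(v, "schema")
  expect_equal(schema$block, c("mldn", "elbp", "shape", "res", "vgg"))
  expect_equal(sum(schema$length), length(v))
  expect_equal(schema$start,
               cumsum(c(1L, utils::head(schema$length, -1L))))
  expect_equal(length(v), 2 * 56 * 16 + 257 + 5 + 32 + 32)
})

test_that("the normalizer z-scores training data and stays frozen", {
  set.seed(33)
  X <- matrix(rnorm(50 * 8, mean = 3, sd = 2), 50, 8)
  X[, 8] <- 1 # constant dimension
  colnames(X) <- sprintf("f%d", 1:8)
  norm <- feature_normalizer(X, sd_floor_quantile = 0)
  Z <- normalize_features(norm, X)
  expect_equal(unname(colMeans(Z[, 1:7])), rep(0, 7), tolerance = 1e-6)
  expect_equal(unname(apply(Z[, 1:7], 2, sd)), rep(1, 7), tolerance = 1e-6)
  expect_equal(unname(Z[, 8]), rep(0, 50)) # constant dims map to 0

  # frozen: applying to new data does not refit but shifts by 5/sd
  Y <- X + 5
  Zy <- normalize_features(norm, Y)
  expect_equal(Zy[, 1:7], Z[, 1:7] + rep(5 / norm$sd[1:7], each = 50),
               tolerance = 1e-9)
})

test_that("relevance weighting attenuates label-independent dimensions", {
  set.seed(34)
  labels <- rep(0:3, each = 25)
  signal <- labels + rnorm(100, sd = 0.3)
  noise <- matrix(rnorm(100 * 5), 100, 5)
  X <- cbind(signal, noise)
  colnames(X) <- sprintf("f%d", 1:6)
  norm <- feature_normalizer(X, labels = labels)
  expect_gt(norm$weight[1], max(norm$weight[-1]) * 5)
  expect_equal(sqrt(mean(norm$weight^2)), 1, tolerance = 1e-9)
})

test_that("normalizer state round-trips through JSON", {
  set.seed(35)
  X <- matrix(rnorm(40), 10, 4)
  colnames(X) <- sprintf("f%d", 1:4)
  norm <- feature_normalizer(X, labels = rep(0:1, 5))
  path <- tempfile(fileext = ".json")
  write_normalizer(norm, path)
  back <- read_normalizer(path)
  expect_equal(back$mean, unname(norm$mean), ignore_attr = TRUE)
  expect_equal(back$sd, unname(norm$sd), ignore_attr = TRUE)
  expect_equal(back$weight, unname(norm$weight), ignore_attr = TRUE)
  expect_equal(normalize_features(back, X), normalize_features(norm, X),
               ignore_attr = TRUE)
})
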