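test_that("stochastic pooling probabilities follow the positive-part rule", {
  expect_equal(stochastic_probabilities(c(1, 2, 3, 4)),
               c(0.1, 0.2, 0.3, 0.4))
  expect_equal(stochastic_probabilities(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(stochastic_probabilities(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(stochastic_probabilities(c(-1, -5, 2)), c(0, 0, 1))
  expect_equal(sum(stochastic_probabilities(runif(9))), 1)
  expect_error(stochastic_probabilities(numeric(0)),
               class = "lungsev_input_error")
})

test_that("mixed pooling reduces to max pooling when deterministic", {
  set.seed(3)
  fm <- matrix(runif(64), 8, 8)
  pooled <- mixed_stochastic_pool(fm, gamma = 1, sample_term = FALSE)
  want <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      want[i, j] <- max(fm[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
    }
  }
  expect_equal(pooled, want)
})

test_that("constant regions pool to 2c with sampling and c without", {
  fm <- matrix(0.3, 4, 4)
  expect_equal(mixed_stochastic_pool(fm, gamma = 1, sample_term = FALSE,
                                     seed = 1),
               matrix(0.3, 2, 2))
  expect_equal(mixed_stochastic_pool(fm, gamma = 0.4, sample_term = TRUE,
                                     seed = 1),
               matrix(0.6, 2, 2))
})

test_that("the pooling expectation identity holds by Monte Carlo (small n)", {
  region <- matrix(c(1, 2, 3, 4), 2, 2)
  draws <- vapply(1:4000, function(i) {
    mixed_stochastic_pool(region, gamma = 1, sample_term = TRUE,
                          seed = i)[1, 1]
  }, numeric(1))
  # E = max + sum p_i a_i = 4 + 3 = 7; se = sd/sqrt(n)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 7), 3 * se + 0.05)
})

test_that("the output activation matches its piecewise definition", {
  expect_equal(hard_tanh_softplus(-5), -1)
  expect_equal(hard_tanh_softplus(-100), -1)
  expect_equal(hard_tanh_softplus(0), 0)
  expect_equal(hard_tanh_softplus(2), 1 + log(1 + exp(2)))
  expect_equal(hard_tanh_softplus(2), 3.126928, tolerance = 1e-6)
  expect_equal(hard_tanh_softplus(1), 2) # middle branch at the joint: 1*(1+1)
  expect_equal(hard_tanh_softplus(0, middle = "ratio"), 0)
  expect_equal(hard_tanh_softplus(-1, middle = "ratio"), -1) # guarded pole
  x <- matrix(c(-3, 0.5, 4), 1, 3)
  expect_equal(dim(hard_tanh_softplus(x)), dim(x))
})

test_that("the activation is bounded below and increasing off the middle branch", {
  lo <- seq(-50, -1.001, length.out = 101)
  hi <- seq(1.001, 50, length.out = 101)
  expect_true(all(hard_tanh_softplus(lo) == -1))
  fh <- hard_tanh_softplus(hi)
  expect_true(all(diff(fh) > 0)) # strictly increasing, unbounded
  expect_gt(fh[101], 50)
  all_x <- seq(-10, 10, by = 0.01)
  expect_true(all(hard_tanh_softplus(all_x) >= -1))
})

test_that("the segmenter has the stated architecture", {
  m <- build_msegnet(input_size = 64, width_multiplier = 1 / 16, seed = 1)
  expect_equal(m$n_conv, 26)
  expect_equal(m$n_pool, 5)
  n_up <- sum(vapply(m$layers, function(l) l$type == "upsample", logical(1)))
  expect_equal(n_up, 5)
  g <- glance(m)
  expect_equal(g$n_conv_layers, 26)
  expect_false(g$trained)
  expect_error(build_msegnet(input_size = 50), class = "lungsev_input_error")
})

test_that("segmentation output matches the input shape and is deterministic", {
  m <- build_msegnet(input_size = 64, seed = 2)
  img <- generate_phantom(phantom_spec(1, 64, seed = 3))$image
  mk1 <- segment(m, img)
  mk2 <- segment(m, img)
  expect_identical(unclass(mk1), unclass(mk2))
  expect_identical(dim(mk1), dim(img))
  expect_true(all(mk1 %in% c(0, 1)))

  img96 <- generate_phantom(phantom_spec(1, 96, seed = 3))$image
  mk3 <- segment(m, img96)
  expect_identical(dim(mk3), c(96L, 96L))
})

test_that("an all-zero-weight model yields a constant mask", {
  m <- build_msegnet(input_size = 32 * 2, seed = 4)
  for (l in lungsev:::param_layers(m$layers)) {
    for (nm in names(l$par)) l$par[[nm]] <- l$par[[nm]] * 0
  }
  img <- matrix(runif(64 * 64), 64, 64)
  mk <- segment(m, img)
  act <- attr(mk, "activation")
  expect_equal(length(unique(as.vector(act))), 1)
  # activation 0 (all-zero conv) sits exactly at the threshold -> all-1 mask
  expect_true(all(mk == 1))
})

test_that("training declines the loss and reproduces under a fixed seed", {
  s <- generate_phantom(phantom_spec(2, 64, seed = 7))
  m1 <- build_msegnet(input_size = 64, seed = 5)
  m1 <- train_segmenter(m1, list(s$image), list(s$lung_mask), epochs = 5,
                        lr = 1e-2, batch_size = 1, seed = 6)
  expect_lt(m1$history$loss[5], m1$history$loss[1])

  m2 <- build_msegnet(input_size = 64, seed = 5)
  m2 <- train_segmenter(m2, list(s$image), list(s$lung_mask), epochs = 5,
                        lr = 1e-2, batch_size = 1, seed = 6)
  expect_identical(m1$history, m2$history)
  expect_error(train_segmenter(m1, list(), list()),
               class = "lungsev_input_error")
})
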