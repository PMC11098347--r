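test_that("attention matches its limits and a two-loop oracle", {
  # single key/value: softmax of a singleton -> output = that value row
  Q <- matrix(rnorm(6), 3, 2)
  V1 <- matrix(c(5, 7), 1, 2)
  out <- scaled_dot_product_attention(Q, matrix(c(1, 1), 1, 2), V1)
  expect_equal(out, matrix(c(5, 7), 3, 2, byrow = TRUE))

  # saturation: scaling Q = K pushes each query onto its best key
  # (unit-norm rows: the best key of each query is itself)
  set.seed(14)
  X <- matrix(rnorm(8), 4, 2)
  X <- X / sqrt(rowSums(X^2))
  V <- diag(4)
  big <- scaled_dot_product_attention(X * 50, X * 50, V)
  expect_equal(max.col(big), 1:4) # each row attends to itself

  Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(12), 3, 4)
  Vv <- matrix(rnorm(6), 3, 2)
  expect_equal(scaled_dot_product_attention(Q, K, Vv),
               oracle_attention(Q, K, Vv), tolerance = 1e-6)
  expect_error(scaled_dot_product_attention(Q, K[, 1:2], Vv),
               class = "lungsev_input_error")
})

test_that("the hybrid activation is the logistic+tanh sum with range (-1, 2)", {
  expect_equal(hybrid_activation(0), 0.5)
  expect_equal(hybrid_activation(100), 2, tolerance = 1e-9)
  expect_equal(hybrid_activation(-100), -1, tolerance = 1e-9)
  x <- seq(-6, 6, by = 0.05)
  expect_true(all(diff(hybrid_activation(x)) > 0))
})

test_that("the Tversky index collapses to soft Dice at chi = 1/2", {
  p <- c(1, 0, 1, 0); ph <- c(1, 0, 1, 0)
  expect_equal(tversky_index(p, ph), 1, tolerance = 1e-5)
  expect_lt(tversky_index(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1e-5)
  set.seed(15)
  for (i in 1:10) {
    p <- runif(12); ph <- runif(12)
    expect_equal(tversky_index(p, ph, 0.5, smooth = 0),
                 2 * sum(p * ph) / (sum(p) + sum(ph)), tolerance = 1e-6)
    # swapping the FP/FN roles while flipping chi leaves the index unchanged
    chi <- runif(1)
    swapped <- sum(p * ph) /
      (sum(p * ph) + (1 - chi) * sum(p * (1 - ph)) + chi * sum((1 - p) * ph))
    expect_equal(tversky_index(p, ph, chi, smooth = 0), swapped,
                 tolerance = 1e-9)
  }
  expect_error(tversky_index(c(2, 0), c(1, 0)), class = "lungsev_input_error")
})

test_that("the Tversky-modulated loss is nonnegative and vanishes at truth", {
  targets <- lungsev:::one_hot(c(0, 1, 2, 3))
  perfect <- (targets * 2 - 1) * 50
  expect_lt(improved_loss(perfect, targets), 1e-4)

  # uniform prediction: hand evaluation of both factors (macro average:
  # target class index 0.25/(0.25 + 0.5*0.75) = 0.4, the three rest
  # classes 0/(0.5*0.25) = 0)
  logits0 <- matrix(0, 1, 4)
  t0 <- lungsev:::one_hot(0L)
  ti <- mean(c(0.25 / (0.25 + 0.5 * 0.75), 0, 0, 0))
  a <- mean(hybrid_activation(logits0) + 1) / 3
  expect_equal(improved_loss(logits0, t0, smooth = 0), (1 - ti) * a,
               tolerance = 1e-9)

  set.seed(16)
  for (i in 1:200) {
    lg <- matrix(rnorm(8, sd = 3), 2, 4)
    tg <- lungsev:::one_hot(sample(0:3, 2, replace = TRUE))
    expect_gte(improved_loss(lg, tg), 0)
  }
  expect_error(improved_loss(matrix(0, 1, 4), matrix(0.5, 1, 4)),
               class = "lungsev_input_error")
})

test_that("the loss decreases along the path from uniform to correct", {
  targets <- lungsev:::one_hot(c(0, 3))
  path <- seq(0, 8, by = 0.5)
  losses <- vapply(path, function(s) {
    improved_loss((targets - 0.5) * s, targets)
  }, numeric(1))
  expect_true(all(diff(losses) < 1e-9))
})

test_that("fire modules concatenate expands and count parameters by formula", {
  set.seed(17)
  fire <- lungsev:::layer_fire(3L, 2L, 4L, 4L, kw = 3L)
  fm <- lungsev:::fmap(matrix(rnorm(30), 10, 3), 1L, 10L, 1L)
  out <- lungsev:::fire_fwd(fire, fm, training = FALSE)
  expect_equal(ncol(out$x), 8) # expand1 + expand3
  expect_equal(c(out$h, out$w), c(1, 10)) # spatial size preserved
  # in*s + s + s*e1 + e1 + 3*s*e3 + e3 (width-1 kernels: 3-tap expand)
  want <- 3 * 2 + 2 + 2 * 4 + 4 + 3 * 2 * 4 + 4
  expect_equal(lungsev:::n_parameters(list(fire)), want)
})

test_that("classifier networks emit 4-class probability rows", {
  sq <- build_sdpa_squeezenet(200, seed = 18)
  dc <- build_dcnn(200, seed = 19)
  X <- matrix(rnorm(400), 2, 200)
  ps <- predict(sq, X); pd <- predict(dc, X)
  expect_equal(dim(ps), c(2L, 4L))
  expect_equal(unname(rowSums(ps)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(rowSums(pd)), c(1, 1), tolerance = 1e-9)
  # at the full assembled feature length the fire-module design is the
  # lighter model
  expect_lt(count_parameters(build_sdpa_squeezenet(1222, seed = 18)),
            count_parameters(build_dcnn(1222, seed = 19)))

  sq2 <- build_sdpa_squeezenet(200, seed = 18)
  expect_equal(sq$layers[[1]]$par, sq2$layers[[1]]$par) # same-seed init
})

test_that("hybrid averaging follows the lowest-index tie rule", {
  h1 <- hybrid_classify(c(0.9, 0.05, 0.03, 0.02), c(0.9, 0.05, 0.03, 0.02))
  expect_equal(h1$label, 0L)
  h2 <- hybrid_classify(c(1, 0, 0, 0), c(0, 0, 0, 1))
  expect_equal(h2$probs[1, ], c(0.5, 0, 0, 0.5))
  expect_equal(h2$label, 0L) # tie broken toward the lower class
  expect_equal(rowSums(h2$probs), 1)
  expect_error(hybrid_classify(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 0, 0)),
               class = "lungsev_input_error")
})

test_that("both branches can overfit a small separable feature set", {
  set.seed(20)
  proto <- matrix(rnorm(4 * 64, sd = 2), 4, 64)
  labels <- rep(0:3, each = 4)
  X <- proto[labels + 1, ] + matrix(rnorm(16 * 64, sd = 0.3), 16, 64)
  fit <- train_hybrid(X, labels, epochs = 200, batch_size = 16, seed = 21)
  pr <- predict(fit, X)
  expect_equal(mean(pr$label == labels), 1)
  expect_named(pr, c("id", sprintf("p%d_a", 0:3), sprintf("p%d_b", 0:3),
                     sprintf("p%d_avg", 0:3), "label"))

  fit2 <- train_hybrid(X, labels, epochs = 5, batch_size = 16, seed = 22)
  fit3 <- train_hybrid(X, labels, epochs = 5, batch_size = 16, seed = 22)
  expect_identical(fit2$history, fit3$history) # seeded determinism
  expect_warning(train_hybrid(X[1:8, ], labels[1:8], epochs = 1,
                              batch_size = 8, seed = 1),
                 "absent")
})
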