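# Numerical gradient checks of the layer framework: every analytic
# gradient is compared against central finite differences on tiny inputs.

num_grad <- function(fun, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (fun(x1) - fun(x2)) / (2 * eps)
  }
  g
}

test_that("backpropagation matches finite differences through a mixed stack", {
  set.seed(40)
  h <- 4L; w <- 4L; b <- 2L; cin <- 2L
  layers <- list(
    lungsev:::layer_conv(cin, 3L), lungsev:::layer_bn(3L),
    lungsev:::layer_relu(), lungsev:::layer_pool("max", 2L, 2L),
    lungsev:::layer_fire(3L, 2L, 2L, 2L), lungsev:::layer_sdpa(),
    lungsev:::layer_gap(), lungsev:::layer_dense(4L, 2L)
  )
  x0 <- matrix(rnorm(h * w * b * cin), h * w * b, cin)
  target <- lungsev:::one_hot(c(0L, 1L), 2L)
  lossfun <- function(xv) {
    fm <- lungsev:::fmap(matrix(xv, h * w * b, cin), h, w, b)
    out <- lungsev:::net_forward(layers, fm, training = TRUE)$out
    lungsev:::softmax_ce_loss(out, target)$loss
  }
  res <- lungsev:::net_forward(layers, lungsev:::fmap(x0, h, w, b),
                               training = TRUE)
  ld <- lungsev:::softmax_ce_loss(res$out, target)
  dx <- lungsev:::net_backward(layers, res$shapes, ld$grad)
  expect_equal(as.vector(dx$x), as.vector(num_grad(lossfun, x0)),
               tolerance = 1e-6)
  # parameter gradients of conv and batch norm
  for (li in c(1L, 2L, 8L)) {
    l <- layers[[li]]
    for (nm in names(l$par)) {
      expect_false(is.null(l$grad[[nm]]))
      W0 <- l$par[[nm]]
      pf <- function(wv) {
        l$par[[nm]] <- if (is.matrix(W0)) matrix(wv, nrow(W0), ncol(W0)) else wv
        on.exit(l$par[[nm]] <- W0)
        lossfun(as.vector(x0))
      }
      expect_equal(as.vector(l$grad[[nm]]),
                   as.vector(num_grad(pf, as.vector(W0))), tolerance = 1e-5)
    }
  }
})

test_that("gradients flow through upsampling, activation, and flatten paths", {
  set.seed(41)
  h <- 4L; w <- 4L; b <- 2L
  layers <- list(
    lungsev:::layer_conv(1L, 2L), lungsev:::layer_pool("mspool", 2L, 2L, 0.6),
    lungsev:::layer_upsample(2L, 2L), lungsev:::layer_conv(2L, 1L),
    lungsev:::layer_hts("product"), lungsev:::layer_flatten(),
    lungsev:::layer_dense(h * w, 2L)
  )
  x0 <- matrix(rnorm(h * w * b) * 0.3, h * w * b, 1)
  target <- lungsev:::one_hot(c(1L, 0L), 2L)
  lossfun <- function(xv) {
    fm <- lungsev:::fmap(matrix(xv, h * w * b, 1), h, w, b)
    out <- lungsev:::net_forward(layers, fm, training = TRUE)$out
    lungsev:::softmax_ce_loss(out, target)$loss
  }
  res <- lungsev:::net_forward(layers, lungsev:::fmap(x0, h, w, b),
                               training = TRUE)
  ld <- lungsev:::softmax_ce_loss(res$out, target)
  dx <- lungsev:::net_backward(layers, res$shapes, ld$grad)
  expect_equal(as.vector(dx$x), as.vector(num_grad(lossfun, x0)),
               tolerance = 1e-6)
})

test_that("the positional attention layer learns an additive embedding", {
  set.seed(42)
  l <- lungsev:::layer_sdpa(positional = TRUE)
  fm <- lungsev:::fmap(matrix(rnorm(12), 6, 2), 1L, 6L, 1L)
  out <- lungsev:::sdpa_fwd(l, fm, training = TRUE)
  expect_equal(dim(l$par$P), c(6L, 2L))
  dl <- lungsev:::sdpa_bwd(l, lungsev:::fmap(matrix(1, 6, 2), 1L, 6L, 1L))
  expect_false(is.null(l$grad$P))
  lossfun <- function(pv) {
    l2 <- lungsev:::layer_sdpa(positional = TRUE)
    l2$par <- list(P = matrix(pv, 6, 2))
    sum(lungsev:::sdpa_fwd(l2, fm, training = FALSE)$x)
  }
  expect_equal(as.vector(l$grad$P),
               as.vector(num_grad(lossfun, as.vector(l$par$P))),
               tolerance = 1e-6)
})

test_that("the Tversky-modulated loss gradient matches finite differences", {
  set.seed(43)
  lg <- matrix(rnorm(12), 3, 4)
  tg <- lungsev:::one_hot(c(0L, 2L, 3L))
  gr <- lungsev:::improved_loss_grad(lg, tg)
  # the activation factor is a detached modulation weight: compare against
  # the derivative of (1 - TI) holding the factor fixed
  a <- mean(hybrid_activation(lg) + 1) / 3
  f_ti <- function(lv) {
    l2 <- matrix(lv, 3, 4)
    p <- lungsev:::softmax_rows(l2)
    ti_k <- vapply(1:4, function(k) {
      tp <- sum(tg[, k] * p[, k]); fp <- sum((1 - tg[, k]) * p[, k])
      fn <- sum(tg[, k] * (1 - p[, k]))
      (tp + 1e-6) / (tp + 0.5 * fp + 0.5 * fn + 1e-6)
    }, numeric(1))
    a * (1 - mean(ti_k))
  }
  expect_equal(as.vector(gr$grad), as.vector(num_grad(f_ti, as.vector(lg))),
               tolerance = 1e-6)
})

test_that("mixed stochastic pooling expectation decomposes as stated", {
  # E[MSpool] = gamma*max + (1-gamma)*mean + sum p_i a_i, Monte Carlo
  set.seed(44)
  region <- matrix(c(0.5, 2, -1, 4), 2, 2)
  gamma <- 0.3
  p <- stochastic_probabilities(region)
  want <- gamma * max(region) + (1 - gamma) * mean(region) +
    sum(p * as.vector(region))
  draws <- vapply(1:4000, function(i) {
    mixed_stochastic_pool(region, gamma = gamma, sample_term = TRUE,
                          seed = i)[1, 1]
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - want), 3 * se + 0.02)
})
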