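# Minimal CNN machinery with explicit backpropagation.
#
# A feature map ("fmap") is a list(x, h, w, b): `x` is a ((b*h*w) x C)
# matrix of activations, rows ordered batch-major then column-major within
# each sample. After global pooling / flattening, activations become plain
# (b x n) matrices. Layers are environments holding parameters, gradients,
# Adam state and the forward cache; networks are lists of layers applied in
# sequence (composite layers cover branching blocks such as fire modules).
# All convolutions are stride-1 'same' with zero padding; resolution
# changes happen in pooling/upsampling layers.

fmap <- function(x, h, w, b) list(x = x, h = h, w = w, b = b)

# ---- index helpers ----------------------------------------------------

# Gather indices mapping each (sample, position, kernel offset) to a row of
# the zero-padded activation matrix. Cached per (h, w, kh, kw, b).
conv_indices <- function(h, w, kh, kw, b) {
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  hp <- h + 2L * ph; wp <- w + 2L * pw
  r <- rep(seq_len(h), times = w) + ph
  c <- rep(seq_len(w), each = h) + pw
  offs <- expand.grid(dr = seq_len(kh) - 1L - ph, dc = seq_len(kw) - 1L - pw)
  idx1 <- matrix(0L, h * w, kh * kw)
  for (o in seq_len(nrow(offs))) {
    idx1[, o] <- (c + offs$dc[o] - 1L) * hp + (r + offs$dr[o])
  }
  samp_off <- rep((seq_len(b) - 1L) * hp * wp, each = h * w)
  idx <- idx1[rep(seq_len(h * w), times = b), , drop = FALSE] + samp_off
  # rows of the unpadded activations inside the padded matrix
  inner <- (c - 1L) * hp + r
  inner_all <- inner[rep(seq_len(h * w), times = b)] + samp_off
  list(idx = idx, inner = inner_all, pad_rows = hp * wp * b)
}

pad_activations <- function(x, ci) {
  xp <- matrix(0, ci$pad_rows, ncol(x))
  xp[ci$inner, ] <- x
  xp
}

# ---- layer constructors ----------------------------------------------

he_init <- function(nin, nout, fan) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan)), nin, nout)
}

layer_conv <- function(cin, cout, kh = 3L, kw = 3L) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"; l$kh <- kh; l$kw <- kw; l$cin <- cin; l$cout <- cout
  l$par <- list(W = he_init(kh * kw * cin, cout, kh * kw * cin),
                b = numeric(cout))
  l
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"; l$momentum <- momentum; l$eps <- eps
  l$par <- list(gamma = rep(1, c), beta = numeric(c))
  l$run_mean <- numeric(c); l$run_var <- rep(1, c)
  l
}

layer_relu <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "relu"; l$par <- list(); l
}

# mode: "max", "avg" or "mspool" (mixed stochastic)
layer_pool <- function(mode, rh = 2L, rw = 2L, gamma = 1) {
  l <- new.env(parent = emptyenv())
  l$type <- "pool"; l$mode <- mode; l$rh <- rh; l$rw <- rw; l$gamma <- gamma
  l$par <- list()
  l
}

layer_upsample <- function(fh = 2L, fw = 2L) {
  l <- new.env(parent = emptyenv())
  l$type <- "upsample"; l$fh <- fh; l$fw <- fw; l$par <- list(); l
}

# Scaled dot-product attention over spatial positions. With
# `positional = TRUE` a learnable positional embedding (positions x
# channels, zero-initialized, lazily sized on first forward) is added to
# the tokens before attention, so that downstream global pooling can read
# position-specific information.
layer_sdpa <- function(positional = FALSE) {
  l <- new.env(parent = emptyenv())
  l$type <- "sdpa"; l$positional <- positional; l$par <- list()
  l
}

layer_gap <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "gap"; l$par <- list(); l
}

layer_flatten <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "flatten"; l$par <- list(); l
}

layer_dense <- function(nin, nout) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"
  l$par <- list(W = he_init(nin, nout, nin), b = numeric(nout))
  l
}

layer_hts <- function(middle = "product") {
  l <- new.env(parent = emptyenv())
  l$type <- "hts"; l$middle <- middle; l$par <- list(); l
}

layer_fire <- function(cin, squeeze, expand1, expand3, kw = 3L) {
  l <- new.env(parent = emptyenv())
  l$type <- "fire"; l$cin <- cin
  l$squeeze <- layer_conv(cin, squeeze, 1L, 1L)
  l$exp1 <- layer_conv(squeeze, expand1, 1L, 1L)
  l$exp3 <- layer_conv(squeeze, expand3, 1L, kw)
  l$par <- list()
  l
}

# ---- forward / backward ----------------------------------------------

conv_fwd <- function(l, fm, training) {
  key <- paste(fm$h, fm$w, fm$b, sep = "x")
  if (is.null(l$ci) || !identical(l$ci_key, key)) {
    l$ci <- conv_indices(fm$h, fm$w, l$kh, l$kw, fm$b)
    l$ci_key <- key
  }
  ci <- l$ci
  xp <- pad_activations(fm$x, ci)
  K <- l$kh * l$kw; C <- l$cin
  xcol <- matrix(0, nrow(fm$x), K * C)
  for (o in seq_len(K)) {
    xcol[, ((o - 1L) * C + 1L):(o * C)] <- xp[ci$idx[, o], , drop = FALSE]
  }
  y <- xcol %*% l$par$W
  y <- sweep(y, 2L, l$par$b, "+")
  if (training) l$cache <- xcol
  fmap(y, fm$h, fm$w, fm$b)
}

conv_bwd <- function(l, dfm) {
  dy <- dfm$x
  l$grad <- list(W = crossprod(l$cache, dy), b = colSums(dy))
  dxcol <- dy %*% t(l$par$W)
  ci <- l$ci; K <- l$kh * l$kw; C <- l$cin
  dxp <- matrix(0, ci$pad_rows, C)
  for (o in seq_len(K)) {
    rows <- ci$idx[, o]
    dxp[rows, ] <- dxp[rows, ] + dxcol[, ((o - 1L) * C + 1L):(o * C)]
  }
  l$cache <- NULL
  fmap(dxp[ci$inner, , drop = FALSE], dfm$h, dfm$w, dfm$b)
}

bn_fwd <- function(l, fm, training) {
  x <- if (is.list(fm)) fm$x else fm
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc^2)
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
  } else {
    mu <- l$run_mean; v <- l$run_var
    xc <- sweep(x, 2L, mu)
  }
  invstd <- 1 / sqrt(v + l$eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, l$par$gamma, "*"), 2L, l$par$beta, "+")
  if (training) { l$cache <- list(xhat = xhat, invstd = invstd) }
  if (is.list(fm)) fmap(y, fm$h, fm$w, fm$b) else y
}

bn_bwd <- function(l, dfm) {
  dy <- if (is.list(dfm)) dfm$x else dfm
  xhat <- l$cache$xhat; invstd <- l$cache$invstd
  n <- nrow(dy)
  l$grad <- list(gamma = colSums(dy * xhat), beta = colSums(dy))
  dxhat <- sweep(dy, 2L, l$par$gamma, "*")
  s1 <- colSums(dxhat); s2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat, 2L, s1 / n) - sweep(xhat, 2L, s2 / n, "*")
  dx <- sweep(dx, 2L, invstd, "*")
  l$cache <- NULL
  if (is.list(dfm)) fmap(dx, dfm$h, dfm$w, dfm$b) else dx
}

relu_fwd <- function(l, fm, training) {
  x <- if (is.list(fm)) fm$x else fm
  y <- pmax(x, 0)
  if (training) l$cache <- x > 0
  if (is.list(fm)) fmap(y, fm$h, fm$w, fm$b) else y
}

relu_bwd <- function(l, dfm) {
  dy <- if (is.list(dfm)) dfm$x else dfm
  dx <- dy * l$cache
  l$cache <- NULL
  if (is.list(dfm)) fmap(dx, dfm$h, dfm$w, dfm$b) else dx
}

# Row indices of the k-th member of each pooling region, clamping the
# replicate-padded edge when h or w is not divisible by the region size.
pool_indices <- function(h, w, b, rh, rw) {
  ho <- as.integer(ceiling(h / rh)); wo <- as.integer(ceiling(w / rw))
  or_ <- rep(seq_len(ho), times = wo)
  oc <- rep(seq_len(wo), each = ho)
  members <- list()
  k <- 0L
  for (dc in seq_len(rw)) {
    for (dr in seq_len(rh)) {
      k <- k + 1L
      r <- pmin(h, (or_ - 1L) * rh + dr)
      c <- pmin(w, (oc - 1L) * rw + dc)
      base <- (c - 1L) * h + r
      members[[k]] <- rep(base, times = b) +
        rep((seq_len(b) - 1L) * h * w, each = ho * wo)
    }
  }
  list(members = members, ho = ho, wo = wo)
}

pool_fwd <- function(l, fm, training, sample_term = FALSE) {
  key <- paste(fm$h, fm$w, fm$b, sep = "x")
  if (is.null(l$pi) || !identical(l$pi_key, key)) {
    l$pi <- pool_indices(fm$h, fm$w, fm$b, l$rh, l$rw)
    l$pi_key <- key
  }
  pi <- l$pi; K <- length(pi$members)
  G <- lapply(pi$members, function(m) fm$x[m, , drop = FALSE])
  mx <- Reduce(pmax, G)
  mn <- Reduce(`+`, G) / K
  y <- switch(l$mode,
    max = mx,
    avg = mn,
    mspool = l$gamma * mx + (1 - l$gamma) * mn
  )
  sel <- NULL
  if (l$mode == "mspool" && sample_term) {
    P <- lapply(G, function(g) pmax(g, 0))
    S <- Reduce(`+`, P)
    zero <- S == 0
    if (any(zero)) { # degenerate regions: uniform probabilities
      for (k in seq_len(K)) P[[k]][zero] <- 1
      S[zero] <- K
    }
    u <- matrix(stats::runif(length(S)), nrow(S), ncol(S)) * S
    cum <- matrix(0, nrow(S), ncol(S))
    chosen <- matrix(FALSE, nrow(S), ncol(S))
    al <- matrix(0, nrow(S), ncol(S))
    sel <- vector("list", K)
    for (k in seq_len(K)) {
      cum <- cum + P[[k]]
      pick <- (u <= cum) & !chosen
      if (k == K) pick <- pick | !chosen
      chosen <- chosen | pick
      sel[[k]] <- pick
      al[pick] <- G[[k]][pick]
    }
    y <- y + al
  }
  if (training) l$cache <- list(G = G, mx = mx, sel = sel, K = K)
  fmap(y, pi$ho, pi$wo, fm$b)
}

pool_bwd <- function(l, dfm, in_h, in_w) {
  dy <- dfm$x
  ca <- l$cache; pi <- l$pi; K <- ca$K
  n_in <- in_h * in_w * dfm$b
  dx <- matrix(0, n_in, ncol(dy))
  taken <- matrix(FALSE, nrow(dy), ncol(dy))
  for (k in seq_len(K)) {
    g <- matrix(0, nrow(dy), ncol(dy))
    if (l$mode %in% c("max", "mspool")) {
      is_max <- (ca$G[[k]] == ca$mx) & !taken
      taken <- taken | is_max
      w_max <- if (l$mode == "max") 1 else l$gamma
      g <- g + w_max * dy * is_max
    }
    if (l$mode == "avg") g <- g + dy / K
    if (l$mode == "mspool") {
      if (l$gamma < 1) g <- g + (1 - l$gamma) * dy / K
      if (!is.null(ca$sel)) g <- g + dy * ca$sel[[k]]
    }
    rows <- pi$members[[k]]
    dup <- duplicated(rows)
    if (any(dup)) { # clamped padding rows appear for several k only at edges
      agg <- rowsum(g, group = rows)
      dx[as.integer(rownames(agg)), ] <- dx[as.integer(rownames(agg)), ] + agg
    } else {
      dx[rows, ] <- dx[rows, ] + g
    }
  }
  l$cache <- NULL
  fmap(dx, in_h, in_w, dfm$b)
}

upsample_fwd <- function(l, fm, training) {
  ho <- fm$h * l$fh; wo <- fm$w * l$fw
  key <- paste(fm$h, fm$w, fm$b, sep = "x")
  if (is.null(l$ui) || !identical(l$ui_key, key)) {
    or_ <- rep(seq_len(ho), times = wo)
    oc <- rep(seq_len(wo), each = ho)
    pr <- (or_ - 1L) %/% l$fh + 1L
    pc <- (oc - 1L) %/% l$fw + 1L
    base <- (pc - 1L) * fm$h + pr
    l$ui <- rep(base, times = fm$b) +
      rep((seq_len(fm$b) - 1L) * fm$h * fm$w, each = ho * wo)
    l$ui_key <- key
  }
  fmap(fm$x[l$ui, , drop = FALSE], ho, wo, fm$b)
}

upsample_bwd <- function(l, dfm, in_h, in_w) {
  agg <- rowsum(dfm$x, group = l$ui)
  dx <- matrix(0, in_h * in_w * dfm$b, ncol(dfm$x))
  dx[as.integer(rownames(agg)), ] <- agg
  fmap(dx, in_h, in_w, dfm$b)
}

# Self-attention over spatial positions with identity Q/K/V projections
# (tokens optionally augmented with a learnable positional embedding).
sdpa_fwd <- function(l, fm, training) {
  n <- fm$h * fm$w
  if (isTRUE(l$positional) && is.null(l$par$P)) {
    l$par <- list(P = matrix(0, n, ncol(fm$x)))
  }
  y <- fm$x
  caches <- vector("list", fm$b)
  for (bi in seq_len(fm$b)) {
    rows <- ((bi - 1L) * n + 1L):(bi * n)
    X <- fm$x[rows, , drop = FALSE]
    if (isTRUE(l$positional)) X <- X + l$par$P
    A <- softmax_rows(tcrossprod(X) / sqrt(ncol(X)))
    y[rows, ] <- A %*% X
    if (training) caches[[bi]] <- list(X = X, A = A)
  }
  if (training) l$cache <- caches
  fmap(y, fm$h, fm$w, fm$b)
}

sdpa_bwd <- function(l, dfm) {
  n <- dfm$h * dfm$w
  dx <- dfm$x
  dP <- if (isTRUE(l$positional)) l$par$P * 0 else NULL
  for (bi in seq_len(dfm$b)) {
    rows <- ((bi - 1L) * n + 1L):(bi * n)
    dO <- dfm$x[rows, , drop = FALSE]
    X <- l$cache[[bi]]$X; A <- l$cache[[bi]]$A
    dV <- crossprod(A, dO)
    dA <- tcrossprod(dO, X)
    dS <- A * (dA - rowSums(dA * A))
    scale <- 1 / sqrt(ncol(X))
    dQ <- dS %*% X * scale
    dK <- crossprod(dS, X) * scale
    dXp <- dQ + dK + dV
    dx[rows, ] <- dXp
    if (!is.null(dP)) dP <- dP + dXp
  }
  if (!is.null(dP)) l$grad <- list(P = dP)
  l$cache <- NULL
  dx <- fmap(dx, dfm$h, dfm$w, dfm$b)
  dx
}

gap_fwd <- function(l, fm, training) {
  n <- fm$h * fm$w
  grp <- rep(seq_len(fm$b), each = n)
  y <- rowsum(fm$x, group = grp) / n
  if (training) l$cache <- list(n = n, b = fm$b)
  y
}

gap_bwd <- function(l, dy, in_h, in_w) {
  n <- l$cache$n
  dx <- dy[rep(seq_len(l$cache$b), each = n), , drop = FALSE] / n
  l$cache <- NULL
  fmap(dx, in_h, in_w, nrow(dy))
}

flatten_fwd <- function(l, fm, training) {
  n <- fm$h * fm$w
  if (training) l$cache <- list(n = n, c = ncol(fm$x), b = fm$b)
  # row b of output = as.vector(x_b) (position-major within channel blocks)
  out <- matrix(0, fm$b, n * ncol(fm$x))
  for (bi in seq_len(fm$b)) {
    rows <- ((bi - 1L) * n + 1L):(bi * n)
    out[bi, ] <- as.vector(fm$x[rows, , drop = FALSE])
  }
  out
}

flatten_bwd <- function(l, dy, in_h, in_w) {
  n <- l$cache$n; cc <- l$cache$c; b <- l$cache$b
  dx <- matrix(0, n * b, cc)
  for (bi in seq_len(b)) {
    rows <- ((bi - 1L) * n + 1L):(bi * n)
    dx[rows, ] <- matrix(dy[bi, ], n, cc)
  }
  l$cache <- NULL
  fmap(dx, in_h, in_w, b)
}

dense_fwd <- function(l, x, training) {
  if (training) l$cache <- x
  sweep(x %*% l$par$W, 2L, l$par$b, "+")
}

dense_bwd <- function(l, dy) {
  l$grad <- list(W = crossprod(l$cache, dy), b = colSums(dy))
  dx <- dy %*% t(l$par$W)
  l$cache <- NULL
  dx
}

hts_fwd <- function(l, fm, training) {
  x <- fm$x
  y <- hard_tanh_softplus(x, middle = l$middle)
  if (training) l$cache <- x
  fmap(y, fm$h, fm$w, fm$b)
}

hts_bwd <- function(l, dfm) {
  x <- l$cache
  d <- hts_derivative(x, l$middle)
  l$cache <- NULL
  fmap(dfm$x * d, dfm$h, dfm$w, dfm$b)
}

fire_fwd <- function(l, fm, training, ...) {
  s <- conv_fwd(l$squeeze, fm, training)
  s$x <- pmax(s$x, 0)
  if (training) l$relu_s <- s$x > 0
  e1 <- conv_fwd(l$exp1, s, training)
  e3 <- conv_fwd(l$exp3, s, training)
  y <- pmax(cbind(e1$x, e3$x), 0)
  if (training) { l$relu_e <- y > 0; l$split <- ncol(e1$x) }
  fmap(y, fm$h, fm$w, fm$b)
}

fire_bwd <- function(l, dfm) {
  dy <- dfm$x * l$relu_e
  k <- l$split
  d1 <- conv_bwd(l$exp1, fmap(dy[, 1:k, drop = FALSE], dfm$h, dfm$w, dfm$b))
  d3 <- conv_bwd(l$exp3, fmap(dy[, -(1:k), drop = FALSE], dfm$h, dfm$w, dfm$b))
  ds <- fmap((d1$x + d3$x) * l$relu_s, dfm$h, dfm$w, dfm$b)
  l$relu_s <- NULL; l$relu_e <- NULL
  conv_bwd(l$squeeze, ds)
}

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1L, max))
  m / rowSums(m)
}

# ---- network-level driver --------------------------------------------

net_forward <- function(layers, input, training = FALSE, sample_term = FALSE) {
  shapes <- vector("list", length(layers))
  x <- input
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (is.list(x) && !is.null(x$h)) shapes[[i]] <- c(x$h, x$w)
    x <- switch(l$type,
      conv = conv_fwd(l, x, training),
      bn = bn_fwd(l, x, training),
      relu = relu_fwd(l, x, training),
      pool = pool_fwd(l, x, training, sample_term),
      upsample = upsample_fwd(l, x, training),
      sdpa = sdpa_fwd(l, x, training),
      gap = gap_fwd(l, x, training),
      flatten = flatten_fwd(l, x, training),
      dense = dense_fwd(l, x, training),
      hts = hts_fwd(l, x, training),
      fire = fire_fwd(l, x, training)
    )
  }
  attr(x, "shapes") <- NULL
  list(out = x, shapes = shapes)
}

net_backward <- function(layers, shapes, dout) {
  dx <- dout
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    sh <- shapes[[i]]
    dx <- switch(l$type,
      conv = conv_bwd(l, dx),
      bn = bn_bwd(l, dx),
      relu = relu_bwd(l, dx),
      pool = pool_bwd(l, dx, sh[1], sh[2]),
      upsample = upsample_bwd(l, dx, sh[1], sh[2]),
      sdpa = sdpa_bwd(l, dx),
      gap = gap_bwd(l, dx, sh[1], sh[2]),
      flatten = flatten_bwd(l, dx, sh[1], sh[2]),
      dense = dense_bwd(l, dx),
      hts = hts_bwd(l, dx),
      fire = fire_bwd(l, dx)
    )
  }
  invisible(dx)
}

# Layers carrying parameters, flattened out of composites.
param_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "fire") {
      out <- c(out, list(l$squeeze, l$exp1, l$exp3))
    } else if (length(l$par)) {
      out <- c(out, list(l))
    }
  }
  out
}

n_parameters <- function(layers) {
  sum(vapply(param_layers(layers),
             function(l) sum(vapply(l$par, length, integer(1))), numeric(1)))
}

# Adam with decoupled weight decay (applied to weight matrices only, not
# biases or batch-norm parameters).
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  for (l in param_layers(layers)) {
    if (is.null(l$grad)) next
    if (is.null(l$m)) {
      l$m <- lapply(l$par, function(p) p * 0)
      l$v <- lapply(l$par, function(p) p * 0)
    }
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$m[[nm]] <- beta1 * l$m[[nm]] + (1 - beta1) * g
      l$v[[nm]] <- beta2 * l$v[[nm]] + (1 - beta2) * g^2
      mhat <- l$m[[nm]] / (1 - beta1^t)
      vhat <- l$v[[nm]] / (1 - beta2^t)
      upd <- mhat / (sqrt(vhat) + eps)
      if (weight_decay > 0 && nm == "W") upd <- upd + weight_decay * l$par[[nm]]
      l$par[[nm]] <- l$par[[nm]] - lr * upd
    }
    l$grad <- NULL
  }
  invisible(NULL)
}

# ---- losses ------------------------------------------------------------

soft_dice_loss <- function(p, target, smooth = 1) {
  num <- 2 * sum(p * target) + smooth
  den <- sum(p) + sum(target) + smooth
  list(loss = 1 - num / den,
       grad = -(2 * target * den - num) / den^2)
}

softmax_ce_loss <- function(logits, onehot) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  eps <- 1e-12
  list(loss = -sum(onehot * log(p + eps)) / n,
       grad = (p - onehot) / n,
       probs = p)
}
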