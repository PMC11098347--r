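# Hybrid four-class severity classifier: an attention-augmented
# SqueezeNet trained with a Tversky-modulated loss, a plain convolutional
# network trained with categorical cross-entropy, and class-probability
# averaging of the two branches. Both consume the assembled feature set
# reshaped to a 1 x L single-channel map processed with width-1 kernels.

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, rows of the attention matrix summing
#' to 1.
#'
#' @param Q Query matrix, `n x d_k`.
#' @param K Key matrix, `m x d_k`.
#' @param V Value matrix, `m x d_v`.
#' @return `n x d_v` output matrix.
#' @export
scaled_dot_product_attention <- function(Q, K, V) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) {
    abort_input("dimension mismatch: need Q n x d, K m x d, V m x d_v.")
  }
  softmax_rows(tcrossprod(Q, K) / sqrt(ncol(Q))) %*% V
}

#' Hybrid logistic + hyperbolic activation
#'
#' `f(x) = 1/(1+exp(-x)) + tanh(x)`: strictly increasing, with range
#' `(-1, 2)`.
#'
#' @param x Numeric vector/matrix.
#' @return Same shape as `x`.
#' @export
hybrid_activation <- function(x) {
  stats::plogis(x) + tanh(x)
}

hybrid_activation_deriv <- function(x) {
  s <- stats::plogis(x)
  s * (1 - s) + 1 / cosh(x)^2
}

#' Tversky index between soft label assignments
#'
#' `TI = sum(p*ph) / (sum(p*ph) + chi*sum((1-p)*ph) + (1-chi)*sum(p*(1-ph)))`
#' with an additive smoothing term in numerator and denominator. For
#' `chi = 0.5` this reduces to the soft Dice index
#' `2*sum(p*ph) / (sum(p) + sum(ph))`.
#'
#' @param p_true,p_hat Arrays of the same shape with entries in `[0,1]`.
#' @param chi Asymmetry weight in `[0,1]` trading false positives against
#'   false negatives (default 1/2).
#' @param smooth Additive stabilizer.
#' @return Scalar in `[0,1]`.
#' @export
tversky_index <- function(p_true, p_hat, chi = 0.5, smooth = 1e-6) {
  if (any(p_true < 0 | p_true > 1) || any(p_hat < 0 | p_hat > 1)) {
    abort_input("probabilities must lie in [0, 1].")
  }
  if (chi < 0 || chi > 1) abort_input("`chi` must lie in [0, 1].")
  tp <- sum(p_true * p_hat)
  fp <- sum((1 - p_true) * p_hat)
  fn <- sum(p_true * (1 - p_hat))
  (tp + smooth) / (tp + chi * fp + (1 - chi) * fn + smooth)
}

check_one_hot <- function(targets) {
  if (!all(targets %in% c(0, 1)) || any(rowSums(targets) != 1)) {
    abort_input("`targets` must be one-hot rows.")
  }
}

#' Tversky-modulated classification loss
#'
#' The training loss of the attention-augmented SqueezeNet branch:
#' `L = (1 - TI) * A`, where `TI` is the one-vs-rest [tversky_index()]
#' between the one-hot targets and `softmax(logits)` computed per class
#' and macro-averaged (the usual multiclass soft-Dice/Tversky
#' construction), and `A = mean(hybrid_activation(logits) + 1) / 3` is the
#' mean hybrid activation of the logits rescaled from its `(-1, 2)` range
#' into `(0, 1)`. Both factors are nonnegative, so `L >= 0`, and `L -> 0`
#' as the prediction saturates to the targets.
#'
#' @param logits `n x 4` score matrix.
#' @param targets `n x 4` one-hot matrix.
#' @param chi,smooth See [tversky_index()].
#' @return Scalar loss.
#' @export
improved_loss <- function(logits, targets, chi = 0.5, smooth = 1e-6) {
  improved_loss_grad(logits, targets, chi, smooth)$loss
}

improved_loss_grad <- function(logits, targets, chi = 0.5, smooth = 1e-6) {
  check_one_hot(targets)
  p <- softmax_rows(logits)
  # Macro-averaged one-vs-rest Tversky index: each class contributes its
  # own index, so a collapse onto a single class keeps a live gradient
  # from the remaining classes (the standard multiclass soft-Dice/Tversky
  # construction).
  tp <- colSums(targets * p)
  fp <- colSums((1 - targets) * p)
  fn <- colSums(targets * (1 - p))
  num <- tp + smooth
  den <- tp + chi * fp + (1 - chi) * fn + smooth
  ti_k <- num / den
  k <- ncol(targets)
  ti <- mean(ti_k)
  f <- hybrid_activation(logits)
  a <- mean(f + 1) / 3
  loss <- (1 - ti) * a

  # The activation factor modulates the gradient magnitude but is not
  # itself differentiated: back-propagating through it opens a degenerate
  # minimum (all logits -> -Inf drives the factor, and hence the loss, to
  # 0 with arbitrary class probabilities). Detaching keeps the Tversky
  # term the optimization target.
  dden <- targets + chi * (1 - targets) - (1 - chi) * targets
  dti_dp <- sweep(targets, 2L, den, "/") -
    sweep(dden, 2L, num / den^2, "*")
  g <- -(a / k) * dti_dp
  dlogits <- p * (g - rowSums(g * p))
  list(loss = loss, grad = dlogits, probs = p, ti = ti)
}

squeezenet_fire_plan <- function(width_multiplier) {
  squeeze <- pmax(2L, as.integer(round(c(16, 16, 32, 32, 48, 48, 64, 64) *
                                         width_multiplier)))
  expand <- pmax(4L, as.integer(round(c(64, 64, 128, 128, 192, 192, 256, 256) *
                                        width_multiplier)))
  list(squeeze = squeeze, expand = expand)
}

#' Build the attention-augmented SqueezeNet severity classifier
#'
#' The assembled feature vector (length `input_dim`) is reshaped to a
#' `1 x input_dim` single-channel map and processed with width-1 kernels:
#' convolution + batch norm, a fire module, max pooling + ReLU + batch
#' norm, three fire modules, average pooling, a scaled dot-product
#' attention layer over the remaining positions (keys = queries = values =
#' the channel vectors plus a learnable positional embedding, so that the
#' global pooling stage can read position-specific information), max
#' pooling, four more fire modules, global average pooling and two fully
#' connected layers onto 4 logits. Fire widths follow the canonical
#' SqueezeNet schedule scaled by `width_multiplier`.
#'
#' @param input_dim Length of the feature vector.
#' @param width_multiplier Channel-width scale (default 0.25).
#' @param seed Initialization seed.
#' @return Object of class `c("sdpa_squeezenet", "lungsev_net")`.
#' @export
build_sdpa_squeezenet <- function(input_dim, width_multiplier = 0.25,
                                  seed = 1L) {
  fp <- squeezenet_fire_plan(width_multiplier)
  c1 <- pmax(4L, as.integer(round(96 * width_multiplier)))
  fire <- function(i, cin) {
    layer_fire(cin, fp$squeeze[i], fp$expand[i], fp$expand[i], kw = 3L)
  }
  layers <- with_seed(seed, {
    ls <- list(layer_conv(1L, c1, 1L, 3L), layer_bn(c1))
    ls <- c(ls, list(fire(1L, c1)))
    cin <- 2L * fp$expand[1]
    ls <- c(ls, list(layer_pool("max", 1L, 4L), layer_relu(), layer_bn(cin)))
    for (i in 2:4) { ls <- c(ls, list(fire(i, cin))); cin <- 2L * fp$expand[i] }
    n_tokens <- as.integer(ceiling(ceiling(input_dim / 4) / 4))
    sdpa <- layer_sdpa(positional = TRUE)
    sdpa$par <- list(P = matrix(0, n_tokens, cin))
    ls <- c(ls, list(layer_pool("avg", 1L, 4L), sdpa,
                     layer_pool("max", 1L, 2L)))
    for (i in 5:8) { ls <- c(ls, list(fire(i, cin))); cin <- 2L * fp$expand[i] }
    hidden <- pmax(8L, as.integer(round(128 * width_multiplier)))
    c(ls, list(layer_gap(), layer_dense(cin, hidden), layer_relu(),
               layer_dense(hidden, 4L)))
  })
  structure(list(layers = layers, input_dim = as.integer(input_dim),
                 width_multiplier = width_multiplier, seed = seed,
                 loss = "tversky_hybrid"),
            class = c("sdpa_squeezenet", "lungsev_net"))
}

#' Build the plain convolutional severity classifier
#'
#' Three blocks of (width-1 convolution + ReLU + max pooling) on the
#' `1 x input_dim` feature map, flattened into two fully connected layers
#' onto 4 logits; trained with categorical cross-entropy.
#'
#' @inheritParams build_sdpa_squeezenet
#' @param channels Channel widths of the three convolution blocks.
#' @param pool Max-pooling window (and stride) of each block.
#' @param hidden Width of the penultimate fully connected layer.
#' @return Object of class `c("dcnn", "lungsev_net")`.
#' @export
build_dcnn <- function(input_dim, channels = c(8L, 16L, 16L), pool = 2L,
                       hidden = 64L, seed = 1L) {
  layers <- with_seed(seed, {
    ls <- list()
    cin <- 1L
    len <- as.integer(input_dim)
    for (ch in channels) {
      ls <- c(ls, list(layer_conv(cin, ch, 1L, 3L), layer_relu(),
                       layer_pool("max", 1L, pool)))
      cin <- ch
      len <- as.integer(ceiling(len / pool))
    }
    c(ls, list(layer_flatten(), layer_dense(len * cin, hidden),
               layer_relu(), layer_dense(hidden, 4L)))
  })
  structure(list(layers = layers, input_dim = as.integer(input_dim),
                 seed = seed, loss = "cross_entropy"),
            class = c("dcnn", "lungsev_net"))
}

#' Number of trainable parameters of a network
#' @param model A built network or segmenter.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  n_parameters(model$layers)
}

features_to_fmap <- function(features, input_dim) {
  m <- feature_matrix(features)
  if (ncol(m) != input_dim) {
    abort_input(sprintf("feature length %d does not match model input %d.",
                        ncol(m), input_dim))
  }
  fmap(matrix(as.vector(t(m)), ncol = 1), 1L, input_dim, nrow(m))
}

net_probs <- function(model, features, training = FALSE) {
  fm <- features_to_fmap(features, model$input_dim)
  res <- net_forward(model$layers, fm, training = training)
  list(probs = softmax_rows(res$out), logits = res$out, shapes = res$shapes)
}

#' Class probabilities from a severity network
#'
#' @param object A built (and normally trained) network.
#' @param features Feature matrix or tibble (`n x input_dim`).
#' @param ... Unused.
#' @return `n x 4` matrix of class probabilities (softmax of the logits).
#' @export
predict.lungsev_net <- function(object, features, ...) {
  net_probs(object, features)$probs
}

#' Average two branch predictions into severity labels
#'
#' Averages two class-probability vectors (or matrices, row-wise) and
#' takes the arg-max of the average as the severity label, breaking ties
#' toward the lowest class index.
#'
#' @param probs_a,probs_b Probability vectors of length 4, or `n x 4`
#'   matrices, rows summing to 1 within 1e-6.
#' @return A list with `probs` (the averaged rows) and `label` (integer
#'   vector in 0..3).
#' @examples
#' hybrid_classify(c(1, 0, 0, 0), c(0, 0, 0, 1))$label  # 0 by the tie rule
#' @export
hybrid_classify <- function(probs_a, probs_b) {
  a <- if (is.matrix(probs_a)) probs_a else matrix(probs_a, nrow = 1)
  b <- if (is.matrix(probs_b)) probs_b else matrix(probs_b, nrow = 1)
  check_same_shape(a, b, c("probs_a", "probs_b"))
  if (any(abs(rowSums(a) - 1) > 1e-6) || any(abs(rowSums(b) - 1) > 1e-6)) {
    abort_input("probability rows must sum to 1.")
  }
  avg <- (a + b) / 2
  list(probs = avg, label = max.col(avg, ties.method = "first") - 1L)
}

train_net <- function(model, features, labels, epochs, lr, batch_size, seed,
                      chi = 0.5, weight_decay = 0, augment_noise = 0,
                      lr_schedule = c("constant", "cosine"),
                      ema_decay = 0.995) {
  lr_schedule <- match.arg(lr_schedule)
  m <- feature_matrix(features)
  y <- one_hot(as.integer(labels))
  losses <- numeric(epochs)
  step <- 0L
  lr0 <- lr
  players <- param_layers(model$layers)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      if (lr_schedule == "cosine") {
        lr <- lr0 * 0.5 * (1 + cos(pi * (ep - 1) / max(1, epochs)))
      }
      ord <- sample.int(nrow(m))
      bl <- c()
      for (start in seq(1L, nrow(m), by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1L, nrow(m))]
        mb <- m[ids, , drop = FALSE]
        if (augment_noise > 0) {
          mb <- mb + matrix(stats::rnorm(length(mb), 0, augment_noise),
                            nrow(mb))
        }
        fm <- features_to_fmap(mb, model$input_dim)
        res <- net_forward(model$layers, fm, training = TRUE)
        ld <- if (model$loss == "cross_entropy") {
          softmax_ce_loss(res$out, y[ids, , drop = FALSE])
        } else {
          improved_loss_grad(res$out, y[ids, , drop = FALSE], chi = chi)
        }
        step <- step + 1L
        net_backward(model$layers, res$shapes, ld$grad)
        adam_step(model$layers, lr, step, weight_decay = weight_decay)
        if (ema_decay > 0) {
          for (l in players) {
            if (is.null(l$ema)) l$ema <- lapply(l$par, function(p) p * 0)
            for (nm in names(l$par)) {
              l$ema[[nm]] <- ema_decay * l$ema[[nm]] +
                (1 - ema_decay) * l$par[[nm]]
            }
          }
        }
        bl <- c(bl, ld$loss)
      }
      losses[ep] <- mean(bl)
    }
  })
  # Polyak averaging: inference uses the (bias-corrected) exponential
  # moving average of the weights, a variance-reduced point on the
  # optimization trajectory.
  if (ema_decay > 0 && step > 0L) {
    corr <- 1 - ema_decay^step
    for (l in players) {
      l$par <- lapply(l$ema, function(p) p / corr)
      l$ema <- NULL
    }
  }
  list(model = model, losses = losses)
}

#' Train the hybrid severity classifier
#'
#' Trains the two branches independently on the same (already normalized)
#' feature table: the attention-augmented SqueezeNet with the
#' Tversky-modulated loss and the plain convolutional network with
#' categorical cross-entropy; predictions average the two branches. A
#' warning (not an error) is raised if some severity class is absent from
#' the training labels.
#'
#' @param features Feature matrix or tibble (`n x L`, n >= 8), normally
#'   the output of [normalize_features()].
#' @param labels Integer labels in 0..3, length n.
#' @param models Optional list with pre-built `sdpa` and `dcnn` networks;
#'   built from `seed` if omitted.
#' @param epochs,lr,batch_size Training schedule. Each may be a scalar
#'   (applied to both branches) or a named vector/list with `sdpa` and
#'   `dcnn` entries for per-branch schedules.
#' @param chi Tversky asymmetry of the SqueezeNet branch loss.
#' @param weight_decay Decoupled weight decay per branch (named vector or
#'   list with `sdpa` and `dcnn`): bounds the logit scale, which the
#'   Tversky-type loss does not penalize on its own.
#' @param augment_noise Standard deviation of Gaussian noise added to the
#'   (normalized) training features each step, a cheap regularizing
#'   augmentation; 0 disables.
#' @param seed Seed for initialization and shuffling.
#' @return Object of class `hybrid_classifier` with the two trained
#'   branches and `$history`, a `train_history` tibble of per-epoch losses
#'   for both branches.
#' @export
train_hybrid <- function(features, labels, models = NULL,
                         epochs = c(sdpa = 30L, dcnn = 60L),
                         lr = 1e-3,
                         batch_size = c(sdpa = 32L, dcnn = 16L),
                         chi = 0.5,
                         weight_decay = c(sdpa = 0.2, dcnn = 0.05),
                         augment_noise = 0.1, seed = 1L) {
  m <- feature_matrix(features)
  labels <- as.integer(labels)
  if (nrow(m) < 8L) abort_input("need at least 8 training samples.")
  if (nrow(m) != length(labels)) {
    abort_input("`features` rows and `labels` length differ.")
  }
  if (!all(0:3 %in% labels)) {
    rlang::warn("some severity classes are absent from the training labels.")
  }
  if (is.null(models)) {
    models <- list(sdpa = build_sdpa_squeezenet(ncol(m), seed = seed),
                   dcnn = build_dcnn(ncol(m), seed = child_seed(seed, 2L)))
  }
  branch_par <- function(x, branch) {
    x <- as.list(x)
    v <- if (!is.null(names(x)) && branch %in% names(x)) x[[branch]] else x[[1]]
    v
  }
  wd <- as.list(weight_decay)
  fit_a <- train_net(models$sdpa, m, labels,
                     epochs = branch_par(epochs, "sdpa"),
                     lr = branch_par(lr, "sdpa"),
                     batch_size = branch_par(batch_size, "sdpa"),
                     seed = child_seed(seed, 11L), chi = chi,
                     weight_decay = wd$sdpa %||% 0,
                     augment_noise = augment_noise)
  fit_b <- train_net(models$dcnn, m, labels,
                     epochs = branch_par(epochs, "dcnn"),
                     lr = branch_par(lr, "dcnn"),
                     batch_size = branch_par(batch_size, "dcnn"),
                     seed = child_seed(seed, 12L),
                     weight_decay = wd$dcnn %||% 0,
                     augment_noise = augment_noise)
  history <- structure(
    dplyr::bind_rows(
      tibble::tibble(epoch = seq_along(fit_a$losses), loss = fit_a$losses,
                     branch = "sdpa_squeezenet"),
      tibble::tibble(epoch = seq_along(fit_b$losses), loss = fit_b$losses,
                     branch = "dcnn")
    ),
    class = c("train_history", class(tibble::tibble()))
  )
  structure(list(sdpa = fit_a$model, dcnn = fit_b$model, history = history,
                 chi = chi, seed = seed),
            class = "hybrid_classifier")
}

#' Predict severity labels with the hybrid classifier
#'
#' @param object A trained [train_hybrid()] classifier.
#' @param features Feature matrix or tibble.
#' @param ... Unused.
#' @return Tibble with per-branch probabilities (`p0_a..p3_a`,
#'   `p0_b..p3_b`), averaged probabilities (`p0_avg..p3_avg`) and the
#'   predicted `label`.
#' @export
predict.hybrid_classifier <- function(object, features, ...) {
  pa <- predict(object$sdpa, features)
  pb <- predict(object$dcnn, features)
  hc <- hybrid_classify(pa, pb)
  out <- tibble::as_tibble(cbind(pa, pb, hc$probs), .name_repair = "minimal")
  names(out) <- c(sprintf("p%d_a", 0:3), sprintf("p%d_b", 0:3),
                  sprintf("p%d_avg", 0:3))
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1) |>
    dplyr::mutate(label = hc$label)
}

#' @export
print.hybrid_classifier <- function(x, ...) {
  cat(sprintf("<hybrid_classifier> squeezenet branch: %s params; dcnn branch: %s params\n",
              format(count_parameters(x$sdpa), big.mark = ","),
              format(count_parameters(x$dcnn), big.mark = ",")))
  invisible(x)
}

#' @export
print.lungsev_net <- function(x, ...) {
  cat(sprintf("<%s> input %d, %s parameters, loss: %s\n", class(x)[1],
              x$input_dim, format(count_parameters(x), big.mark = ","),
              x$loss))
  invisible(x)
}
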