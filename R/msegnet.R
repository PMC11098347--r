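# Encoder-decoder lung-field segmenter: 13 + 13 convolutional layers, five
# mixed stochastic pooling stages in the encoder, nearest-neighbour
# upsampling (no stored pooling indices) in the decoder, and a hard
# tanh-softplus output activation thresholded into a binary mask.

#' Stochastic pooling probabilities of a region
#'
#' `p_i = max(a_i, 0) / sum_k max(a_k, 0)` over the region's activations;
#' if every positive part is zero the probabilities are uniform. The
#' result sums to 1 exactly.
#'
#' @param values Numeric vector (or matrix) of region activations.
#' @return Probability vector of the same length.
#' @examples
#' stochastic_probabilities(c(1, 2, 3, 4))  # 0.1 0.2 0.3 0.4
#' @export
stochastic_probabilities <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0) abort_input("empty pooling region.")
  p <- pmax(v, 0)
  s <- sum(p)
  if (s == 0) rep(1 / length(p), length(p)) else p / s
}

#' Mixed stochastic pooling of a feature map
#'
#' Per pooling region `R`, computes `gamma * max(a) + (1 - gamma) * mean(a)
#' + a_l`, where `a_l` is one activation sampled from the region with the
#' probabilities of [stochastic_probabilities()]. With `sample_term =
#' FALSE` the stochastic addend is dropped, giving the deterministic
#' inference form (for `gamma = 1`, plain max pooling). Edges of maps not
#' divisible by the region size are replicate-padded.
#'
#' @param feature_map Numeric matrix.
#' @param gamma Mixing weight between max (1) and mean (0) pooling.
#' @param region Pooling window as `c(rows, cols)` (default 2x2, stride =
#'   window).
#' @param sample_term Include the sampled activation addend?
#' @param seed Optional seed for the sampling draw.
#' @return Pooled matrix of dimensions `ceiling(dim(feature_map)/region)`.
#' @examples
#' mixed_stochastic_pool(matrix(1:4, 2, 2), gamma = 1, sample_term = FALSE) # 4
#' @export
mixed_stochastic_pool <- function(feature_map, gamma = 1, region = c(2L, 2L),
                                  sample_term = TRUE, seed = NULL) {
  check_image(feature_map, "feature_map")
  if (gamma < 0 || gamma > 1) abort_input("`gamma` must lie in [0, 1].")
  l <- layer_pool("mspool", rh = region[1], rw = region[2], gamma = gamma)
  fm <- fmap(matrix(as.vector(feature_map), ncol = 1),
             nrow(feature_map), ncol(feature_map), 1L)
  run <- function() pool_fwd(l, fm, training = FALSE, sample_term = sample_term)
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  matrix(out$x, out$h, out$w)
}

#' Hard tanh-softplus activation
#'
#' Piecewise output activation: `-1` for `x < -1`; the middle branch for
#' `-1 <= x <= 1` (default parse `x * (x + 1)`; alternate parse
#' `x / (x + 1)`, with the pole at `x = -1` guarded to return `-1`); and
#' `1 + log(1 + exp(x))` for `x > 1`. Bounded below by -1 everywhere and
#' unbounded, strictly increasing, above the upper threshold.
#'
#' @param x Numeric vector, matrix or array.
#' @param middle `"product"` (`x*(x+1)`) or `"ratio"` (`x/(x+1)`).
#' @return Same shape as `x`.
#' @examples
#' hard_tanh_softplus(c(-5, 0, 2))  # -1, 0, 1 + log(1 + e^2)
#' @export
hard_tanh_softplus <- function(x, middle = c("product", "ratio")) {
  middle <- match.arg(middle)
  out <- x
  lo <- x < -1
  hi <- x > 1
  mid <- !lo & !hi
  out[lo] <- -1
  if (middle == "product") {
    out[mid] <- x[mid] * (x[mid] + 1)
  } else {
    xm <- x[mid]
    om <- ifelse(xm == -1, -1, xm / (xm + 1))
    out[mid] <- om
  }
  xh <- x[hi]
  out[hi] <- 1 + ifelse(xh > 30, xh, log1p(exp(xh)))
  out
}

# Derivative of hard_tanh_softplus, used by backprop.
hts_derivative <- function(x, middle = "product") {
  d <- x * 0
  mid <- x >= -1 & x <= 1
  hi <- x > 1
  if (middle == "product") {
    d[mid] <- 2 * x[mid] + 1
  } else {
    xm <- x[mid]
    d[mid] <- ifelse(xm == -1, 0, 1 / (xm + 1)^2)
  }
  d[hi] <- stats::plogis(x[hi])
  d
}

segnet_channel_plan <- function(width_multiplier) {
  plan <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
  pmax(2L, as.integer(round(plan * width_multiplier)))
}

#' Build the modified encoder-decoder segmenter
#'
#' Encoder: five blocks of (3x3 conv + batch norm + ReLU) with the
#' 2-2-3-3-3 layer plan and channel widths 64-64-128-...-512 scaled by
#' `width_multiplier`, each block closed by a mixed stochastic pooling
#' stage (2x2). Decoder: mirror image with nearest-neighbour upsampling in
#' place of pooling (no stored pooling indices) and batch norm + ReLU after
#' every convolution except the last, which maps to a single channel fed
#' through the hard tanh-softplus activation. 13 + 13 = 26 convolutional
#' layers and 5 pooling / 5 upsampling stages in total.
#'
#' @param input_size Square input side in pixels; must be divisible by 32.
#' @param width_multiplier Fraction of the canonical channel widths
#'   (desk-scale default 1/16).
#' @param gamma Mixing weight of the pooling stages.
#' @param middle Middle-branch parse of the output activation (see
#'   [hard_tanh_softplus()]).
#' @param seed Seed for the parameter initialization.
#' @return An object of class `msegnet`.
#' @export
build_msegnet <- function(input_size = 64L, width_multiplier = 1 / 16,
                          gamma = 1, middle = c("product", "ratio"),
                          seed = 1L) {
  middle <- match.arg(middle)
  if (input_size %% 32L != 0L) {
    abort_input("`input_size` must be divisible by 32.")
  }
  widths <- segnet_channel_plan(width_multiplier)
  blocks <- c(2L, 2L, 3L, 3L, 3L)
  layers <- with_seed(seed, {
    ls <- list()
    cin <- 1L
    ix <- 1L
    for (b in seq_along(blocks)) {
      for (k in seq_len(blocks[b])) {
        cout <- widths[ix]; ix <- ix + 1L
        ls <- c(ls, list(layer_conv(cin, cout), layer_bn(cout), layer_relu()))
        cin <- cout
      }
      ls <- c(ls, list(layer_pool("mspool", 2L, 2L, gamma)))
    }
    dec_widths <- rev(c(1L, widths[-length(widths)])) # mirrored encoder inputs
    dec_blocks <- rev(blocks)
    ix <- 1L
    for (b in seq_along(dec_blocks)) {
      ls <- c(ls, list(layer_upsample(2L, 2L)))
      for (k in seq_len(dec_blocks[b])) {
        cout <- dec_widths[ix]; ix <- ix + 1L
        last <- ix > length(dec_widths)
        ls <- c(ls, list(layer_conv(cin, cout)))
        if (!last) ls <- c(ls, list(layer_bn(cout), layer_relu()))
        cin <- cout
      }
    }
    c(ls, list(layer_hts(middle)))
  })
  structure(
    list(layers = layers, input_size = as.integer(input_size),
         gamma = gamma, middle = middle,
         width_multiplier = width_multiplier, seed = seed,
         n_conv = sum(vapply(layers, function(l) l$type == "conv", logical(1))),
         n_pool = sum(vapply(layers, function(l) l$type == "pool", logical(1))),
         history = NULL),
    class = "msegnet"
  )
}

# Forward pass to the raw activation map for a batch of equally sized
# square images (list of matrices), deterministic unless sample_term.
msegnet_activation <- function(model, imgs, training = FALSE,
                               sample_term = FALSE) {
  n <- model$input_size
  b <- length(imgs)
  x <- matrix(0, n * n * b, 1)
  for (i in seq_len(b)) {
    im <- resize_image(imgs[[i]], n, n)
    x[((i - 1L) * n * n + 1L):(i * n * n), 1L] <- as.vector(im)
  }
  net_forward(model$layers, fmap(x, n, n, b), training = training,
              sample_term = sample_term)
}

#' Segment an image into a binary lung mask
#'
#' Runs the segmenter deterministically (stochastic pooling addend off)
#' and thresholds the output activation. The default threshold 0 is the
#' midpoint of the activation's saturation range `[-1, 1 + softplus)`.
#' Images whose size differs from the model input are resized for the
#' forward pass and the mask is resized back.
#'
#' @param model An [build_msegnet()] model (trained or freshly built).
#' @param img Numeric image matrix in `[0,1]`.
#' @param threshold Activation threshold for mask membership.
#' @return Binary mask matrix of the same dimensions as `img`, with the raw
#'   activation attached as attribute `"activation"`.
#' @export
segment <- function(model, img, threshold = 0) {
  check_image(img)
  res <- msegnet_activation(model, list(img))
  n <- model$input_size
  act <- matrix(res$out$x, n, n)
  mask <- matrix(as.numeric(act >= threshold), n, n)
  if (!identical(dim(img), dim(mask))) {
    mask <- resize_image(mask, nrow(img), ncol(img), method = "nearest")
  }
  attr(mask, "activation") <- act
  mask
}

#' Train the segmenter on (image, mask) pairs
#'
#' Minimizes a soft-Dice loss on the sigmoid of the final convolution's
#' output (the input of the hard tanh-softplus activation). Because the
#' output activation is sign-preserving (`f(x) >= 0` iff `x >= 0`), this
#' surrogate agrees exactly with the inference rule `activation >=
#' threshold` at the default threshold 0, while avoiding the activation's
#' saturated lower branch where gradients vanish. Optimization is Adam
#' with seeded shuffling. The stochastic pooling addend is active during
#' training and disabled at inference; after the last epoch the batch-norm
#' running statistics are recalibrated with one deterministic
#' (sample-term-off) pass over the training images so that inference-mode
#' normalization matches the deterministic pooling path.
#'
#' @param model An `msegnet` model; its parameters are updated in place
#'   (layers are reference objects) and the updated model is returned.
#' @param images List of image matrices.
#' @param masks List of binary masks, same length and sizes.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling shuffling and pooling draws.
#' @return The trained model, with `$history` set to a tibble of per-epoch
#'   mean losses (class `train_history`).
#' @export
train_segmenter <- function(model, images, masks, epochs = 10L, lr = 5e-3,
                            batch_size = 8L, seed = 1L) {
  if (length(images) == 0L || length(images) != length(masks)) {
    abort_input("`images` and `masks` must be non-empty lists of equal length.")
  }
  n <- model$input_size
  masks_r <- lapply(masks, function(m) {
    r <- resize_image(m, n, n, method = "nearest")
    as.vector(r)
  })
  losses <- numeric(epochs)
  step <- 0L
  body <- model$layers[-length(model$layers)] # final hard tanh-softplus is sign-preserving
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(images))
      batch_losses <- c()
      for (start in seq(1L, length(ord), by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1L, length(ord))]
        b <- length(ids)
        n2 <- n * n
        x <- matrix(0, n2 * b, 1)
        for (i in seq_len(b)) {
          x[((i - 1L) * n2 + 1L):(i * n2), 1L] <-
            as.vector(resize_image(images[[ids[i]]], n, n))
        }
        res <- net_forward(body, fmap(x, n, n, b), training = TRUE,
                           sample_term = TRUE)
        p <- stats::plogis(res$out$x)
        target <- unlist(masks_r[ids], use.names = FALSE)
        ld <- soft_dice_loss(as.vector(p), target)
        dact <- matrix(ld$grad * p * (1 - p), ncol = 1)
        step <- step + 1L
        net_backward(body, res$shapes,
                     fmap(dact, res$out$h, res$out$w, res$out$b))
        adam_step(body, lr, step)
        batch_losses <- c(batch_losses, ld$loss)
      }
      losses[ep] <- mean(batch_losses)
    }
    recalibrate_bn(model, images)
  })
  model$history <- structure(
    tibble::tibble(epoch = seq_len(epochs), loss = losses,
                   branch = "segmenter"),
    class = c("train_history", class(tibble::tibble()))
  )
  model
}

# One deterministic full-batch pass that resets every batch-norm layer's
# running statistics to the statistics of the deterministic pooling path.
recalibrate_bn <- function(model, images, max_images = 32L) {
  imgs <- images[seq_len(min(length(images), max_images))]
  bns <- Filter(function(l) l$type == "bn", model$layers)
  saved <- lapply(bns, function(l) l$momentum)
  for (l in bns) l$momentum <- 1
  invisible(msegnet_activation(model, imgs, training = TRUE,
                               sample_term = FALSE))
  for (i in seq_along(bns)) {
    bns[[i]]$momentum <- saved[[i]]
    bns[[i]]$cache <- NULL
  }
  invisible(model)
}

#' @export
print.msegnet <- function(x, ...) {
  cat(sprintf(paste0("<msegnet> input %dx%d, %d conv layers, %d pooling ",
                     "stages, %s parameters%s\n"),
              x$input_size, x$input_size, x$n_conv, x$n_pool,
              format(n_parameters(x$layers), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}
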