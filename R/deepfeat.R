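# Deep feature extractors: seeded, forward-only ResNet- and VGG16-style
# backbones at configurable desk-scale widths, plus assembly of the full
# feature set [mldn | elbp | shape | deep] with a frozen z-score
# normalizer. Backbone weights default to seeded random initialization
# (optionally loadable from file); normalization inside the backbones is
# parameter-free per-channel standardization, so extraction is pure and
# deterministic.

# Per-channel standardization of a feature map (no state, no mutation).
feat_norm <- function(fm, eps = 1e-5) {
  mu <- colMeans(fm$x)
  v <- colMeans(sweep(fm$x, 2L, mu)^2)
  fmap(sweep(sweep(fm$x, 2L, mu), 2L, sqrt(v + eps), "/"), fm$h, fm$w, fm$b)
}

backbone_widths <- function(base, width_multiplier) {
  pmax(2L, as.integer(round(base * width_multiplier)))
}

#' Build a deep-feature backbone
#'
#' Constructs a seeded feature extractor of one of two families:
#' \describe{
#'   \item{`"resnet"`}{A stem convolution followed by four stages of
#'     residual blocks (two 3x3 convolutions with per-channel
#'     standardization and ReLU, an identity skip sum -- 1x1-projected when
#'     the width changes -- and a closing ReLU), max pooling between
#'     stages, global average pooling and a linear projection to
#'     `feature_dim`.}
#'   \item{`"vgg16"`}{The 13-convolution 2-2-3-3-3 plan with max pooling
#'     after each block, global average pooling of the final activations
#'     and a fully connected projection to `feature_dim`.}
#' }
#' Channel widths are the canonical plans scaled by `width_multiplier`.
#' Weights are drawn from a seeded He-normal initialization; no pretrained
#' weights are downloaded.
#'
#' @param family `"resnet"` or `"vgg16"`.
#' @param width_multiplier Fraction of canonical channel widths, in (0, 1].
#' @param input_size Square input side for feature extraction.
#' @param feature_dim Length of the output feature vector (>= 8).
#' @param seed Seed for the weight initialization.
#' @return An object of class `backbone`.
#' @export
build_backbone <- function(family = c("resnet", "vgg16"),
                           width_multiplier = 0.25, input_size = 64L,
                           feature_dim = 32L, seed = 1L) {
  family <- match.arg(family)
  if (width_multiplier <= 0 || width_multiplier > 1) {
    abort_input("`width_multiplier` must lie in (0, 1].")
  }
  if (feature_dim < 8) abort_input("`feature_dim` must be >= 8.")
  obj <- with_seed(seed, {
    if (family == "resnet") {
      ch <- backbone_widths(c(64, 128, 256, 512), width_multiplier)
      stem <- layer_conv(1L, ch[1])
      stages <- vector("list", 4L)
      cin <- ch[1]
      for (s in 1:4) {
        proj <- if (cin != ch[s]) layer_conv(cin, ch[s], 1L, 1L) else NULL
        stages[[s]] <- list(conv1 = layer_conv(cin, ch[s]),
                            conv2 = layer_conv(ch[s], ch[s]),
                            proj = proj)
        cin <- ch[s]
      }
      head <- layer_dense(cin, feature_dim)
      list(stem = stem, stages = stages, head = head, widths = ch)
    } else {
      plan <- backbone_widths(c(64, 64, 128, 128, 256, 256, 256,
                                512, 512, 512, 512, 512, 512),
                              width_multiplier)
      blocks <- c(2L, 2L, 3L, 3L, 3L)
      convs <- list(); cin <- 1L
      for (wdt in plan) {
        convs <- c(convs, list(layer_conv(cin, wdt)))
        cin <- wdt
      }
      head <- layer_dense(cin, feature_dim)
      list(convs = convs, blocks = blocks, head = head, widths = plan)
    }
  })
  structure(
    c(obj, list(family = family, width_multiplier = width_multiplier,
                input_size = as.integer(input_size),
                feature_dim = as.integer(feature_dim), seed = seed)),
    class = "backbone"
  )
}

resnet_block_forward <- function(block, fm) {
  h <- conv_fwd(block$conv1, fm, training = FALSE)
  h <- feat_norm(h)
  h$x <- pmax(h$x, 0)
  h <- conv_fwd(block$conv2, h, training = FALSE)
  h <- feat_norm(h)
  skip <- if (is.null(block$proj)) fm else conv_fwd(block$proj, fm, FALSE)
  fmap(pmax(skip$x + h$x, 0), fm$h, fm$w, fm$b)
}

backbone_forward <- function(backbone, fm) {
  pool <- layer_pool("max", 2L, 2L)
  if (backbone$family == "resnet") {
    x <- conv_fwd(backbone$stem, fm, FALSE)
    x <- feat_norm(x)
    x$x <- pmax(x$x, 0)
    for (s in 1:4) {
      if (s > 1) x <- pool_fwd(layer_pool("max", 2L, 2L), x, FALSE)
      x <- resnet_block_forward(backbone$stages[[s]], x)
    }
    g <- gap_fwd(layer_gap(), x, FALSE)
    dense_fwd(backbone$head, g, FALSE)
  } else {
    x <- fm
    i <- 0L
    for (b in seq_along(backbone$blocks)) {
      for (k in seq_len(backbone$blocks[b])) {
        i <- i + 1L
        x <- conv_fwd(backbone$convs[[i]], x, FALSE)
        x <- feat_norm(x)
        x$x <- pmax(x$x, 0)
      }
      x <- pool_fwd(layer_pool("max", 2L, 2L), x, FALSE)
    }
    g <- gap_fwd(layer_gap(), x, FALSE)
    dense_fwd(backbone$head, g, FALSE)
  }
}

#' Extract deep features from an image
#'
#' Runs the backbone forward on the (resized) image and returns the
#' fixed-length feature vector. Deterministic for fixed weights; the
#' backbone is never mutated.
#'
#' @param backbone A [build_backbone()] handle.
#' @param img Numeric image matrix in `[0,1]`.
#' @return Named numeric vector of length `feature_dim` (prefix `res_` or
#'   `vgg_`).
#' @export
extract_deep_features <- function(backbone, img) {
  check_image(img)
  n <- backbone$input_size
  im <- resize_image(img, n, n)
  fm <- fmap(matrix(as.vector(im), ncol = 1), n, n, 1L)
  out <- as.vector(backbone_forward(backbone, fm))
  if (any(!is.finite(out))) {
    rlang::abort("non-finite deep features: internal error.",
                 class = "lungsev_internal_error")
  }
  prefix <- if (backbone$family == "resnet") "res" else "vgg"
  stats::setNames(out, sprintf("%s_%02d", prefix, seq_along(out)))
}

#' Number of convolutional layers in a backbone
#' @param backbone A [build_backbone()] handle.
#' @return Integer count.
#' @export
n_conv_layers <- function(backbone) {
  if (backbone$family == "resnet") {
    1L + sum(vapply(backbone$stages, function(s) {
      2L + as.integer(!is.null(s$proj))
    }, integer(1)))
  } else {
    length(backbone$convs)
  }
}

#' Assemble the full feature set
#'
#' Concatenates the four feature blocks in the fixed order
#' (directional-number patterns, binary-pattern histogram + entropy, shape,
#' deep features) and records the block schema (name, offset, length) as an
#' attribute, so the layout round-trips through serialization.
#'
#' @param mldn,elbp Named numeric vectors from [mldn_descriptor()] /
#'   [elbp_feature()].
#' @param shape One-row tibble from [shape_features()].
#' @param res,vgg Named numeric vectors from [extract_deep_features()].
#' @return Named numeric vector with attribute `"schema"` (a tibble).
#' @export
assemble_feature_set <- function(mldn, elbp, shape, res, vgg) {
  shape_v <- stats::setNames(as.numeric(shape[1, ]),
                             paste0("shape_", names(shape)))
  blocks <- list(mldn = mldn, elbp = elbp, shape = shape_v,
                 res = res, vgg = vgg)
  lens <- vapply(blocks, length, integer(1))
  out <- unlist(blocks, use.names = TRUE)
  names(out) <- unlist(lapply(blocks, names), use.names = FALSE)
  attr(out, "schema") <- tibble::tibble(
    block = names(blocks),
    start = cumsum(c(1L, utils::head(lens, -1L))),
    length = lens
  )
  out
}

#' Extract the full feature set for one image
#'
#' Convenience wrapper computing all four blocks on a segmented image
#' (image restricted to its mask).
#'
#' @param img Image matrix in `[0,1]`.
#' @param mask Binary segmentation mask, same shape.
#' @param backbones List with elements `res` and `vgg` from
#'   [build_backbone()].
#' @param grid MLDN pooling grid.
#' @return Named feature vector (see [assemble_feature_set()]).
#' @export
extract_feature_set <- function(img, mask, backbones, grid = 4L) {
  seg <- img * mask
  assemble_feature_set(
    mldn = mldn_descriptor(img, mask, grid = grid),
    elbp = elbp_feature(img, mask),
    shape = shape_features(mask),
    res = extract_deep_features(backbones$res, seg),
    vgg = extract_deep_features(backbones$vgg, seg)
  )
}

#' Feature table for a set of images
#'
#' Maps [extract_feature_set()] over images and masks and binds the
#' results into a tibble, one row per image.
#'
#' @param images List of image matrices.
#' @param masks List of binary masks, same length.
#' @param backbones List with `res` and `vgg` backbones.
#' @param labels Optional integer labels added as a `label` column.
#' @param grid MLDN pooling grid.
#' @return Tibble with `id` (and `label` if given) plus one column per
#'   feature dimension.
#' @export
extract_features <- function(images, masks, backbones, labels = NULL,
                             grid = 4L) {
  rows <- purrr::map2(images, masks, function(im, mk) {
    v <- extract_feature_set(im, mk, backbones, grid = grid)
    tibble::as_tibble(as.list(v))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
  if (!is.null(labels)) {
    out <- dplyr::mutate(out, label = as.integer(labels), .after = "id")
  }
  out
}

#' Fit a frozen z-score feature normalizer
#'
#' Per-dimension centering and scaling statistics fit on training data
#' only. Two stabilizations guard the plain z-score on high-dimensional
#' descriptor vectors:
#' \itemize{
#'   \item the per-dimension standard deviation is floored at a train-set
#'     quantile of the positive standard deviations, so near-constant
#'     dimensions (rare histogram bins) cannot blow up to huge z-scores;
#'     exactly constant dimensions map to 0;
#'   \item when training `labels` are supplied, each dimension is
#'     additionally scaled by a supervised relevance weight: the fraction
#'     of its train-set variance explained by the class labels (the
#'     correlation ratio of a one-way ANOVA), raised to
#'     `relevance_exponent` and normalized to unit root-mean-square.
#'     Dimensions carrying no class signal are attenuated relative to
#'     informative ones.
#' }
#' The resulting transform is a fixed affine map (invertible on the
#' non-constant dimensions given the stored state) and is frozen: applying
#' it never refits.
#'
#' @param x Numeric matrix or feature tibble (non-feature columns `id`,
#'   `label` are ignored).
#' @param labels Optional integer class labels (length `nrow(x)`) enabling
#'   the relevance weighting.
#' @param sd_floor_quantile Quantile of the positive standard deviations
#'   used as the scale floor (0 disables the floor).
#' @param relevance_exponent Exponent applied to the variance-explained
#'   ratio.
#' @return An object of class `feature_normalizer`.
#' @export
feature_normalizer <- function(x, labels = NULL, sd_floor_quantile = 0.5,
                               relevance_exponent = 1) {
  m <- feature_matrix(x)
  mu <- colMeans(m)
  sd_ <- apply(m, 2L, stats::sd)
  sd_[!is.finite(sd_)] <- 0
  pos <- sd_[sd_ > 0]
  if (sd_floor_quantile > 0 && length(pos)) {
    sd_[sd_ > 0] <- pmax(sd_[sd_ > 0],
                         stats::quantile(pos, sd_floor_quantile))
  }
  sd_[sd_ == 0] <- 1
  weight <- rep(1, ncol(m))
  if (!is.null(labels)) {
    z <- sweep(sweep(m, 2L, mu), 2L, sd_, "/")
    labels <- as.integer(labels)
    grp <- split(seq_along(labels), labels)
    gmeans <- vapply(grp, function(ix) colMeans(z[ix, , drop = FALSE]),
                     numeric(ncol(z)))
    n_g <- vapply(grp, length, integer(1))
    overall <- colMeans(z)
    ssb <- rowSums(sweep(gmeans, 2L, n_g, "*") * gmeans) -
      length(labels) * overall^2
    sst <- colSums(sweep(z, 2L, overall)^2)
    eta <- ifelse(sst > 0, pmax(0, ssb) / sst, 0)
    weight <- eta^relevance_exponent
    rms <- sqrt(mean(weight^2))
    if (rms > 0) weight <- weight / rms
  }
  structure(list(mean = mu, sd = sd_, weight = weight,
                 names = colnames(m)),
            class = "feature_normalizer")
}

#' Apply a fitted feature normalizer
#'
#' @param normalizer A [feature_normalizer()].
#' @param x Feature matrix or tibble.
#' @return Numeric matrix of scaled features (same row order).
#' @export
normalize_features <- function(normalizer, x) {
  m <- feature_matrix(x)
  if (!is.null(normalizer$names) && !is.null(colnames(m))) {
    m <- m[, normalizer$names, drop = FALSE]
  }
  z <- sweep(sweep(m, 2L, normalizer$mean), 2L, normalizer$sd, "/")
  if (!is.null(normalizer$weight)) z <- sweep(z, 2L, normalizer$weight, "*")
  z
}

feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  drop_cols <- intersect(c("id", "label"), colnames(x))
  as.matrix(dplyr::select(x, -dplyr::any_of(drop_cols)))
}

#' Write / read normalizer state as JSON
#' @param normalizer A [feature_normalizer()].
#' @param path File path.
#' @return `read_normalizer` returns the restored normalizer.
#' @export
write_normalizer <- function(normalizer, path) {
  jsonlite::write_json(unclass(normalizer), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(st$mean), sd = as.numeric(st$sd),
                 weight = as.numeric(st$weight), names = st$names),
            class = "feature_normalizer")
}
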