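# broom-style tidiers and ggplot2 autoplot methods for the package's
# result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted segmenter
#'
#' @param x A trained [build_msegnet()] model.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `branch`.
#' @method tidy msegnet
#' @export
tidy.msegnet <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), loss = numeric(),
                          branch = character()))
  }
  tibble::as_tibble(x$history)
}

#' One-row summary of a segmenter
#'
#' @param x An `msegnet` model.
#' @param ... Unused.
#' @return Tibble with architecture counts, parameter count and final
#'   training loss.
#' @method glance msegnet
#' @export
glance.msegnet <- function(x, ...) {
  tibble::tibble(
    input_size = x$input_size,
    n_conv_layers = x$n_conv,
    n_pool_stages = x$n_pool,
    n_parameters = n_parameters(x$layers),
    trained = !is.null(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)]
  )
}

#' Tidy the training history of the hybrid classifier
#'
#' @param x A [train_hybrid()] fit.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `branch` (one row per epoch and
#'   branch).
#' @method tidy hybrid_classifier
#' @export
tidy.hybrid_classifier <- function(x, ...) {
  tibble::as_tibble(x$history)
}

#' One-row summary of the hybrid classifier
#'
#' @param x A [train_hybrid()] fit.
#' @param ... Unused.
#' @return Tibble with per-branch parameter counts and final losses.
#' @method glance hybrid_classifier
#' @export
glance.hybrid_classifier <- function(x, ...) {
  h <- x$history
  last <- function(br) {
    v <- h$loss[h$branch == br]
    if (length(v)) v[length(v)] else NA_real_
  }
  tibble::tibble(
    n_parameters_sdpa = count_parameters(x$sdpa),
    n_parameters_dcnn = count_parameters(x$dcnn),
    final_loss_sdpa = last("sdpa_squeezenet"),
    final_loss_dcnn = last("dcnn"),
    chi = x$chi
  )
}

#' One-row summary of a deep-feature backbone
#'
#' @param x A [build_backbone()] handle.
#' @param ... Unused.
#' @return Tibble with family, depth, width and parameter count.
#' @method glance backbone
#' @export
glance.backbone <- function(x, ...) {
  n_par <- if (x$family == "resnet") {
    layers <- c(list(x$stem, x$head),
                unlist(lapply(x$stages, function(s) {
                  Filter(Negate(is.null), s[c("conv1", "conv2", "proj")])
                }), recursive = FALSE))
    n_parameters(layers)
  } else {
    n_parameters(c(x$convs, list(x$head)))
  }
  tibble::tibble(
    family = x$family,
    n_conv_layers = n_conv_layers(x),
    width_multiplier = x$width_multiplier,
    feature_dim = x$feature_dim,
    n_parameters = n_par
  )
}

#' Plot a phantom slice with its ground-truth masks
#'
#' Renders the grayscale slice with the lung-field boundary and lesion
#' region overlaid.
#'
#' @param object A [generate_phantom()] sample.
#' @param show_masks Overlay the lung and lesion masks?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phantom_sample
#' @export
autoplot.phantom_sample <- function(object, show_masks = TRUE, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$image)),
                           col = seq_len(ncol(object$image)))
  df$intensity <- as.vector(object$image)[
    (df$col - 1L) * nrow(object$image) + df$row]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Phantom slice (severity %d)", object$label),
                  x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  if (show_masks && sum(object$lesion_mask) > 0) {
    les <- df[as.vector(object$lesion_mask)[
      (df$col - 1L) * nrow(object$image) + df$row] == 1, ]
    p <- p + ggplot2::geom_tile(data = les, fill = "red", alpha = 0.25)
  }
  p
}

#' Plot a training-loss history
#'
#' @param object A `train_history` tibble (from `$history` of a trained
#'   model, [tidy.msegnet()] or [tidy.hybrid_classifier()]).
#' @param ... Unused.
#' @return A ggplot object with one loss curve per branch.
#' @method autoplot train_history
#' @export
autoplot.train_history <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                       colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "training loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay a predicted mask on an image
#'
#' @param img Grayscale image matrix.
#' @param mask Binary mask of the same shape.
#' @param truth Optional reference mask, drawn as a second overlay.
#' @return A ggplot object.
#' @export
plot_mask_overlay <- function(img, mask, truth = NULL) {
  check_image(img); check_mask(mask)
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  at <- function(m) as.vector(m)[(df$col - 1L) * nrow(img) + df$row]
  df$intensity <- at(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_tile(data = df[at(mask) == 1, ], fill = "cyan",
                       alpha = 0.25) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_tile(data = df[at(truth) == 1, ], fill = "yellow",
                                alpha = 0.15)
  }
  p
}
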