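#' Specification of a synthetic CT phantom slice
#'
#' Bundles and validates the parameters controlling one synthetic chest-CT
#' phantom: a square grayscale slice containing a bright soft-tissue thorax,
#' two dark elliptical lung fields, and (for non-negative severity labels)
#' lesion textures drawn inside the lung fields.
#'
#' Severity labels follow the four-class coding used throughout the package:
#' 0 negative, 1 air-space consolidation (dense, bright, filled opacities),
#' 2 crazy paving (hazy patches overlaid with a bright reticular grid),
#' 3 ground-glass opacity (hazy patches only).
#'
#' @param label Severity label, integer in `0:3`.
#' @param image_size Side of the square slice in pixels (>= 32).
#' @param noise_sigma Standard deviation of additive Gaussian intensity
#'   noise, on the `[0,1]` intensity scale.
#' @param lesion_count Number of lesion blobs to draw for labels 1-3.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   full specification.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_phantom_dataset()]
#' @export
phantom_spec <- function(label, image_size = 128L, noise_sigma = 0.05,
                         lesion_count = 3L, seed = 1L) {
  if (length(label) != 1L || !label %in% 0:3) {
    abort_input("`label` must be a single integer in 0..3.")
  }
  if (length(image_size) != 1L || is.na(image_size) || image_size < 32) {
    abort_input("`image_size` must be >= 32.")
  }
  if (length(noise_sigma) != 1L || is.na(noise_sigma) || noise_sigma < 0) {
    abort_input("`noise_sigma` must be >= 0.")
  }
  if (length(lesion_count) != 1L || lesion_count < 0) {
    abort_input("`lesion_count` must be >= 0.")
  }
  structure(
    list(label = as.integer(label), image_size = as.integer(image_size),
         noise_sigma = as.numeric(noise_sigma),
         lesion_count = as.integer(lesion_count), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Filled ellipse mask on an n x n grid; center/axes in pixel units.
ellipse_mask <- function(n, cy, cx, ry, rx) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1
}

# Reference intensities of the phantom tissue classes, on the [0,1] scale.
phantom_levels <- function() {
  c(air = 0.05, thorax = 0.75, lung = 0.15,
    consolidation = 0.85, haze = 0.45, grid = 0.80)
}

#' Generate one synthetic CT phantom
#'
#' Draws a deterministic, seeded phantom slice together with its exact
#' ground-truth lung-field mask and lesion mask. Lung fields are two
#' axis-aligned ellipses whose centers and semi-axes are jittered within
#' +/-10% of canonical positions. Lesion texture depends on the severity
#' label: consolidation (label 1) is filled at a high intensity (above the
#' thorax mean), crazy paving (label 2) is a mid-intensity haze overlaid
#' with bright lattice lines at a fixed 8-pixel spacing, ground-glass
#' (label 3) is the haze alone, and negative slices (label 0) carry no
#' lesion. Gaussian noise of `noise_sigma` is added last and the image is
#' clipped to `[0,1]`.
#'
#' @param spec A [phantom_spec()].
#' @param grid_spacing Spacing in pixels of the crazy-paving lattice.
#' @return An object of class `phantom_sample`: a list with elements
#'   `image` (numeric matrix in `[0,1]`), `lung_mask` and `lesion_mask`
#'   (binary matrices, `lesion_mask` a subset of `lung_mask`), `label`,
#'   and `spec`.
#' @examples
#' s <- generate_phantom(phantom_spec(label = 2, image_size = 64, seed = 7))
#' range(s$image)
#' sum(s$lesion_mask * (1 - s$lung_mask))  # lesion confined to the lungs
#' @export
generate_phantom <- function(spec, grid_spacing = 8L) {
  if (!inherits(spec, "phantom_spec")) {
    spec <- do.call(phantom_spec, as.list(spec))
  }
  n <- spec$image_size
  lv <- phantom_levels()
  with_seed(spec$seed, {
    jit <- function(x) x * stats::runif(1, 0.9, 1.1)
    thorax <- ellipse_mask(n, n * 0.52, n * 0.50, n * 0.44, n * 0.46)
    lungL <- ellipse_mask(n, jit(n * 0.52), jit(n * 0.32),
                          jit(n * 0.27), jit(n * 0.15))
    lungR <- ellipse_mask(n, jit(n * 0.52), jit(n * 0.68),
                          jit(n * 0.27), jit(n * 0.15))
    lung <- (lungL | lungR) & thorax
    img <- matrix(lv["air"], n, n)
    img[thorax] <- lv["thorax"]
    img[lung] <- lv["lung"]

    lesion <- matrix(FALSE, n, n)
    if (spec$label > 0L && spec$lesion_count > 0L) {
      inside <- which(lung)
      for (i in seq_len(spec$lesion_count)) {
        ctr <- inside[sample.int(length(inside), 1L)]
        cy <- (ctr - 1L) %% n + 1L
        cx <- (ctr - 1L) %/% n + 1L
        ry <- stats::runif(1, 0.06, 0.12) * n
        rx <- stats::runif(1, 0.06, 0.12) * n
        lesion <- lesion | ellipse_mask(n, cy, cx, ry, rx)
      }
      lesion <- lesion & lung
      if (spec$label == 1L) {
        img[lesion] <- lv["consolidation"]
      } else {
        img[lesion] <- lv["haze"]
        if (spec$label == 2L) {
          r <- matrix(seq_len(n), n, n)
          c <- matrix(seq_len(n), n, n, byrow = TRUE)
          lattice <- (r %% grid_spacing == 0L) | (c %% grid_spacing == 0L)
          img[lesion & lattice] <- lv["grid"]
        }
      }
    }
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
    }
    structure(
      list(image = clip01(img),
           lung_mask = matrix(as.numeric(lung), n, n),
           lesion_mask = matrix(as.numeric(lesion), n, n),
           label = spec$label, spec = spec),
      class = "phantom_sample"
    )
  })
}

#' Generate a balanced phantom dataset
#'
#' Produces `4 * n_per_class` phantoms with a balanced severity-label
#' histogram. Each sample receives a child seed derived deterministically
#' from the master seed (counter-based), so the whole dataset is
#' reproducible from one integer and individual samples can be regenerated
#' independently.
#'
#' @param n_per_class Number of phantoms per severity class (>= 1).
#' @param image_size,noise_sigma,lesion_count Forwarded to [phantom_spec()].
#' @param seed Master seed.
#' @return A list with `samples` (list of `phantom_sample`) and `manifest`,
#'   a tibble with columns `id`, `filename`, `mask_filename`, `label`,
#'   `seed`.
#' @examples
#' ds <- generate_phantom_dataset(2, image_size = 48, seed = 3)
#' dplyr::count(ds$manifest, label)
#' @export
generate_phantom_dataset <- function(n_per_class, image_size = 128L,
                                     noise_sigma = 0.05, lesion_count = 3L,
                                     seed = 1L) {
  if (length(n_per_class) != 1L || n_per_class < 1) {
    abort_input("`n_per_class` must be >= 1.")
  }
  labels <- rep(0:3, each = n_per_class)
  idx <- seq_along(labels)
  seeds <- vapply(idx, function(i) child_seed(seed, i), integer(1))
  samples <- purrr::map2(labels, seeds, function(lb, sd) {
    generate_phantom(phantom_spec(label = lb, image_size = image_size,
                                  noise_sigma = noise_sigma,
                                  lesion_count = lesion_count, seed = sd))
  })
  manifest <- tibble::tibble(
    id = idx,
    filename = sprintf("phantom_%03d.png", idx),
    mask_filename = sprintf("phantom_%03d_mask.png", idx),
    label = as.integer(labels),
    seed = seeds
  )
  list(samples = samples, manifest = manifest)
}

#' Write a phantom dataset to disk
#'
#' Writes each image and its lung mask as 8-bit grayscale PNG plus the
#' manifest as CSV, matching the layout the pipeline reads back.
#'
#' @param dataset Result of [generate_phantom_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest with file paths resolved.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- dataset$manifest
  for (i in seq_len(nrow(m))) {
    write_gray_image(dataset$samples[[i]]$image, file.path(dir, m$filename[i]))
    write_mask(dataset$samples[[i]]$lung_mask, file.path(dir, m$mask_filename[i]))
  }
  readr::write_csv(m, file.path(dir, "manifest.csv"))
  invisible(m)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %dx%d, label %d, lung %d px, lesion %d px\n",
              nrow(x$image), ncol(x$image), x$label,
              sum(x$lung_mask), sum(x$lesion_mask)))
  invisible(x)
}
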