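# File I/O, dataset splitting and the staged pipeline driver binding
# simulate -> preprocess -> segment -> extract -> train -> classify ->
# evaluate together.

#' Read / write grayscale images and masks
#'
#' Images are stored as 8-bit PNG or 8/16-bit TIFF (by file extension) and
#' normalized to `[0,1]` in memory; writing restores the integer range, so
#' a round trip is exact up to one quantization step. Masks are
#' thresholded at 0.5 on read.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param img,mask Numeric matrix in `[0,1]` / binary matrix.
#' @param bits Bit depth for TIFF output (8 or 16; PNG is written 8-bit).
#' @return `read_gray_image`/`read_mask` return a matrix; writers return
#'   the path invisibly.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("cannot read '%s'.", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort_input(sprintf("unsupported image format '%s' (%s).", ext, path))
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else {
      abort_input(sprintf("'%s' is not single-channel grayscale.", path))
    }
  }
  img
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(img, path, bits = 8L) {
  check_image(img)
  ext <- tolower(tools::file_ext(path))
  img <- clip01(img)
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits))
  } else {
    abort_input(sprintf("unsupported image format '%s'.", ext))
  }
  invisible(path)
}

#' @rdname read_gray_image
#' @export
read_mask <- function(path) {
  m <- read_gray_image(path)
  matrix(as.numeric(m >= 0.5), nrow(m), ncol(m))
}

#' @rdname read_gray_image
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  write_gray_image(mask, path)
}

#' Read / write feature tables
#'
#' CSV with a header schema; values round-trip at full double precision.
#'
#' @param features Feature tibble (as from [extract_features()]).
#' @param path CSV path.
#' @return `read_features` returns a tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Train/test split sizes by the floor rule
#'
#' `n_train = floor(train_fraction * n_total)`, remainder to test. With
#' 3345 slices this reproduces the splits 2007/1338 (60%), 2341/1004
#' (70%), 2676/669 (80%) and 3010/335 (90%).
#'
#' @param n_total Total number of samples.
#' @param train_fraction Fraction in (0, 1).
#' @return One-row tibble with `n_train`, `n_test`.
#' @export
split_dataset <- function(n_total, train_fraction) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_input("`train_fraction` must lie strictly between 0 and 1.")
  }
  n_train <- floor(train_fraction * n_total)
  tibble::tibble(n_train = as.integer(n_train),
                 n_test = as.integer(n_total - n_train))
}

# Stratified (by label) index split using the floor rule per class.
stratified_split <- function(labels, train_fraction, seed) {
  with_seed(seed, {
    tr <- unlist(lapply(sort(unique(labels)), function(k) {
      ids <- which(labels == k)
      take <- floor(train_fraction * length(ids))
      sample(ids, take)
    }))
    sort(tr)
  })
}

#' Pipeline configuration
#'
#' Builds the nested configuration driving [run_pipeline()], merging user
#' overrides into the desk-scale defaults. Any subset of the fields can be
#' supplied; see the method vignette for the meaning and units of each.
#'
#' @param out_dir Output directory for all artifacts.
#' @param ... Named overrides of the defaults (nested lists are merged
#'   field-wise), e.g. `simulate = list(n_per_class = 10)`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, ...) {
  defaults <- list(
    out_dir = out_dir,
    seed = 1L,
    train_fraction = 0.75,
    simulate = list(n_per_class = 10L, image_size = 64L, noise_sigma = 0.05,
                    lesion_count = 3L),
    preprocess = list(window = 5L, noise_variance = "auto",
                      variant = "linear"),
    segmenter = list(width_multiplier = 1 / 16, gamma = 1, epochs = 10L,
                     lr = 5e-3, batch_size = 8L, threshold = 0),
    features = list(grid = 4L, feature_dim = 32L, width_multiplier = 0.25),
    classifier = list(epochs = c(sdpa = 30L, dcnn = 60L), lr = 1e-3,
                      batch_size = c(sdpa = 32L, dcnn = 16L), chi = 0.5,
                      augment_noise = 0.1)
  )
  overrides <- list(...)
  merge_lists <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  structure(merge_lists(defaults, overrides), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()]; must
#'   contain `out_dir`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) abort_input("config must set `out_dir`.")
  do.call(pipeline_config, c(list(out_dir = y$out_dir),
                             y[setdiff(names(y), "out_dir")]))
}

#' Run the full severity pipeline on synthetic phantoms
#'
#' Executes the staged pipeline: simulate phantoms, denoise them, train
#' the segmenter on the training split and segment every slice, extract
#' the feature set inside the predicted masks, train the hybrid
#' classifier, predict the test split and evaluate. Every stage writes its
#' artifacts under `config$out_dir` (regenerating deterministically
#' whenever an artifact is missing) and the whole run is a deterministic
#' function of the configuration, so re-runs reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the evaluation `report`, the
#'   `predictions` tibble, segmentation scores and the trained models.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort_input("`config` must be a `pipeline_config`.")
  }
  dir_ <- config$out_dir
  if (!dir.exists(dir_)) dir.create(dir_, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_hash <- rlang::hash(unclass(config))
  stamp <- list(seed = config$seed, config_hash = cfg_hash,
                version = as.character(utils::packageVersion("lungsev")))
  jsonlite::write_json(stamp, file.path(dir_, "run_info.json"),
                       auto_unbox = TRUE)

  # -- simulate ---------------------------------------------------------
  data_dir <- file.path(dir_, "data")
  sim <- config$simulate
  ds <- generate_phantom_dataset(sim$n_per_class, sim$image_size,
                                 sim$noise_sigma, sim$lesion_count,
                                 seed = child_seed(config$seed, 1L))
  if (!file.exists(file.path(data_dir, "manifest.csv"))) {
    say("stage simulate: writing %d phantoms", nrow(ds$manifest))
    write_phantom_dataset(ds, data_dir)
  }
  manifest <- ds$manifest
  labels <- manifest$label
  images <- lapply(ds$samples, `[[`, "image")
  truth_masks <- lapply(ds$samples, `[[`, "lung_mask")

  # -- preprocess -------------------------------------------------------
  pre_dir <- file.path(dir_, "pre")
  if (!dir.exists(pre_dir)) dir.create(pre_dir)
  pp <- config$preprocess
  say("stage preprocess: improved Wiener filtering (%s variant)", pp$variant)
  pre_images <- lapply(images, improved_wiener, window = pp$window,
                       noise_variance = pp$noise_variance,
                       variant = pp$variant)
  quality <- dplyr::bind_rows(
    purrr::map2(images, pre_images, image_quality)
  ) |> dplyr::mutate(id = manifest$id, .before = 1)
  readr::write_csv(quality, file.path(pre_dir, "quality.csv"))
  for (i in seq_along(pre_images)) {
    fn <- file.path(pre_dir, manifest$filename[i])
    if (!file.exists(fn)) write_gray_image(pre_images[[i]], fn)
  }

  # -- split ------------------------------------------------------------
  tr <- stratified_split(labels, config$train_fraction,
                         seed = child_seed(config$seed, 2L))
  te <- setdiff(seq_along(labels), tr)

  # -- segment ----------------------------------------------------------
  sg <- config$segmenter
  say("stage segment: training segmenter on %d slices", length(tr))
  seg_model <- build_msegnet(input_size = sim$image_size,
                             width_multiplier = sg$width_multiplier,
                             gamma = sg$gamma,
                             seed = child_seed(config$seed, 3L))
  seg_model <- train_segmenter(seg_model, images = pre_images[tr],
                               masks = truth_masks[tr], epochs = sg$epochs,
                               lr = sg$lr, batch_size = sg$batch_size,
                               seed = child_seed(config$seed, 4L))
  mask_dir <- file.path(dir_, "masks_pred")
  if (!dir.exists(mask_dir)) dir.create(mask_dir)
  pred_masks <- lapply(pre_images, function(im) {
    segment(seg_model, im, threshold = sg$threshold)
  })
  for (i in seq_along(pred_masks)) {
    fn <- file.path(mask_dir, manifest$mask_filename[i])
    if (!file.exists(fn)) write_mask(pred_masks[[i]], fn)
  }
  seg_scores <- tibble::tibble(
    id = manifest$id,
    split = ifelse(manifest$id %in% tr, "train", "test"),
    dice = purrr::map2_dbl(pred_masks, truth_masks, dice),
    jaccard = purrr::map2_dbl(pred_masks, truth_masks, jaccard)
  )
  readr::write_csv(seg_scores, file.path(dir_, "segmentation_scores.csv"))

  # -- extract ----------------------------------------------------------
  ftr <- config$features
  say("stage extract: feature set for %d slices", length(images))
  backbones <- list(
    res = build_backbone("resnet", ftr$width_multiplier, sim$image_size,
                         ftr$feature_dim, seed = child_seed(config$seed, 5L)),
    vgg = build_backbone("vgg16", ftr$width_multiplier, sim$image_size,
                         ftr$feature_dim, seed = child_seed(config$seed, 6L))
  )
  features <- extract_features(pre_images, pred_masks, backbones,
                               labels = labels, grid = ftr$grid)
  write_features(features, file.path(dir_, "features.csv"))

  # -- train classifier -------------------------------------------------
  cl <- config$classifier
  say("stage train: hybrid classifier on %d samples", length(tr))
  normalizer <- feature_normalizer(features[tr, ], labels = labels[tr])
  write_normalizer(normalizer, file.path(dir_, "normalizer.json"))
  x_tr <- normalize_features(normalizer, features[tr, ])
  clf <- train_hybrid(x_tr, labels[tr], epochs = cl$epochs, lr = cl$lr,
                      batch_size = cl$batch_size, chi = cl$chi,
                      augment_noise = cl$augment_noise,
                      seed = child_seed(config$seed, 7L))

  # -- classify ---------------------------------------------------------
  x_te <- normalize_features(normalizer, features[te, ])
  preds <- predict(clf, x_te) |>
    dplyr::mutate(id = manifest$id[te], truth = labels[te])
  readr::write_csv(preds, file.path(dir_, "predictions.csv"))

  # -- evaluate ---------------------------------------------------------
  report_tbl <- severity_report(preds$label, preds$truth)
  report <- list(
    seed = config$seed, config_hash = cfg_hash,
    version = stamp$version,
    n_train = length(tr), n_test = length(te),
    segmentation = list(
      mean_dice_test = mean(seg_scores$dice[seg_scores$split == "test"]),
      mean_jaccard_test = mean(seg_scores$jaccard[seg_scores$split == "test"])
    ),
    classification = report_tbl
  )
  jsonlite::write_json(report, file.path(dir_, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("pipeline complete: test accuracy %.3f, mean test dice %.3f",
      report_tbl$accuracy[report_tbl$class == "macro"],
      report$segmentation$mean_dice_test)
  invisible(list(report = report, predictions = preds,
                 segmentation = seg_scores, quality = quality,
                 segmenter = seg_model, classifier = clf,
                 normalizer = normalizer, train_ids = tr, test_ids = te))
}
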