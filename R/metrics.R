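#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are in perfect agreement and
#' score 1 (flagged via the `"degenerate"` attribute).
#'
#' @param a,b Binary matrices of identical shape.
#' @return Fraction in `[0,1]`.
#' @export
dice <- function(a, b) {
  check_mask(a, "a"); check_mask(b, "b"); check_same_shape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(structure(1, degenerate = TRUE))
  2 * sum(a * b) / (sa + sb)
}

#' Jaccard index between two binary masks
#'
#' `|A n B| / |A u B|`; both-empty convention 1, as for [dice()]. The two
#' overlap scores obey `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @return Fraction in `[0,1]`.
#' @export
jaccard <- function(a, b) {
  check_mask(a, "a"); check_mask(b, "b"); check_same_shape(a, b)
  uni <- sum(pmax(a, b))
  if (uni == 0) return(structure(1, degenerate = TRUE))
  sum(a * b) / uni
}

#' One-vs-rest confusion counts
#'
#' Binarizes a 4-class prediction task against a chosen positive class and
#' tallies true/false positives/negatives.
#'
#' @param pred,truth Integer label vectors in `0:3`, equal length.
#' @param positive_class The class treated as positive.
#' @return One-row tibble with columns `class`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth, positive_class) {
  if (length(pred) != length(truth)) {
    abort_input("`pred` and `truth` must have equal length.")
  }
  if (!all(pred %in% 0:3) || !all(truth %in% 0:3)) {
    abort_input("labels must lie in 0..3.")
  }
  p <- pred == positive_class
  t <- truth == positive_class
  tibble::tibble(
    class = positive_class,
    tp = sum(p & t), tn = sum(!p & !t),
    fp = sum(p & !t), fn = sum(!p & t)
  )
}

#' Full 4x4 confusion matrix
#'
#' @inheritParams confusion_counts
#' @return A 4x4 integer matrix, rows = true class 0..3, columns =
#'   predicted class.
#' @export
confusion_matrix <- function(pred, truth) {
  if (!all(pred %in% 0:3) || !all(truth %in% 0:3)) {
    abort_input("labels must lie in 0..3.")
  }
  table(factor(truth, 0:3), factor(pred, 0:3)) |>
    unclass() |> matrix(4, 4, dimnames = list(true = 0:3, pred = 0:3))
}

#' Nine classification metrics from confusion counts
#'
#' Computes accuracy, precision, sensitivity (recall / TPR), specificity,
#' false-negative rate, false-positive rate, F-measure, the Matthews
#' correlation coefficient and negative predictive value from TP/TN/FP/FN
#' counts, using the textbook formulas (e.g. F-measure =
#' `TP / (TP + (FP + FN)/2)`, the harmonic mean of precision and
#' sensitivity). All rates are returned as fractions; multiply sensitivity
#' and specificity by 100 for percentage presentation. Any metric whose
#' denominator is zero is reported as 0 and the row is flagged degenerate.
#'
#' @param counts A one-row data frame with columns `tp`, `tn`, `fp`, `fn`
#'   (as from [confusion_counts()]), or a named list/vector.
#' @return One-row tibble with the nine metrics plus `degenerate`.
#' @examples
#' classification_metrics(list(tp = 884, tn = 0, fp = 0, fn = 120))$sensitivity
#' @export
classification_metrics <- function(counts) {
  cc <- as.list(counts)
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  if (any(is.na(c(tp, tn, fp, fn))) || any(c(tp, tn, fp, fn) < 0)) {
    abort_input("counts must be nonnegative numbers named tp, tn, fp, fn.")
  }
  if (tp + tn + fp + fn < 1) abort_input("at least one count must be positive.")
  degenerate <- FALSE
  frac <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  mcc_den <- sqrt((tp + fp) * (fn + tp) * (tn + fp) * (tn + fn))
  tibble::tibble(
    accuracy = frac(tn + tp, fp + fn + tp + tn),
    precision = frac(tp, fp + tp),
    sensitivity = frac(tp, fn + tp),
    specificity = frac(tn, fp + tn),
    fnr = frac(fn, fn + tp),
    fpr = frac(fp, fp + tn),
    f_measure = frac(tp, tp + (fp + fn) / 2),
    mcc = frac(tp * tn - fp * fn, mcc_den),
    npv = frac(tn, tn + fn),
    degenerate = degenerate
  )
}

#' Per-class and macro metric report for 4-class predictions
#'
#' Convenience wrapper: one-vs-rest [classification_metrics()] for each
#' severity class plus their unweighted macro average and the overall
#' multiclass accuracy.
#'
#' @inheritParams confusion_counts
#' @return Tibble with one row per class and a `"macro"` row.
#' @export
severity_report <- function(pred, truth) {
  rows <- purrr::map(0:3, function(k) {
    m <- classification_metrics(confusion_counts(pred, truth, k))
    dplyr::mutate(m, class = as.character(k), .before = 1)
  })
  per_class <- dplyr::bind_rows(rows)
  macro <- per_class |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean)) |>
    dplyr::mutate(class = "macro", .before = 1,
                  degenerate = any(per_class$degenerate))
  macro$accuracy <- mean(pred == truth) # multiclass accuracy for the macro row
  dplyr::bind_rows(per_class, macro)
}
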