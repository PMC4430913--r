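## Pixel-level evaluation metrics for segmentation results.

#' Confusion counts between a predicted and a truth mask
#'
#' @param pred,truth logical matrices of equal shape.
#' @return list of class `confusion_counts` with `Tp`, `Tn`, `Fp`, `Fn`
#'   and `q` (total pixel count); `Tp + Tn + Fp + Fn == q`.
#' @export
confusion_counts <- function(pred, truth) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  structure(list(Tp = sum(pred & truth), Tn = sum(!pred & !truth),
                 Fp = sum(pred & !truth), Fn = sum(!pred & truth),
                 q = length(pred)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Computes accuracy `(Tp+Tn)/q`, precision `Tp/(Tp+Fp)`, sensitivity
#' `Tp/(Tp+Fn)`, specificity `Tn/(Tn+Fp)` and the normalized sum of
#' false detections `eps_F = (Fp+Fn)/(2q)`. A metric whose denominator
#' is zero is reported as `NA` (undefined), never coerced to 0 or 1.
#'
#' @param cc a [confusion_counts()] (or a list with fields `Tp`, `Tn`,
#'   `Fp`, `Fn`, `q`).
#' @return named list `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `eps_F`.
#' @export
segmentation_metrics <- function(cc) {
  if (is.null(cc$q) || cc$q == 0) stop("q = 0: no pixels to evaluate")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = safe(cc$Tp + cc$Tn, cc$q),
       precision = safe(cc$Tp, cc$Tp + cc$Fp),
       sensitivity = safe(cc$Tp, cc$Tp + cc$Fn),
       specificity = safe(cc$Tn, cc$Tn + cc$Fp),
       eps_F = (cc$Fp + cc$Fn) / (2 * cc$q))
}

#' Dice overlap between two masks
#' @param a,b logical matrices/arrays of equal shape.
#' @return Dice coefficient `2|A n B| / (|A| + |B|)`.
#' @export
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

#' Voxel recall of a tracked model against a truth mask
#' @param pred,truth logical arrays of equal shape.
#' @return `|pred n truth| / |truth|`.
#' @export
voxel_recall <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (sum(truth) == 0) return(NA_real_)
  sum(pred & truth) / sum(truth)
}
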