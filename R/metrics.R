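#' Pixel-level confusion counts
#'
#' Compares a predicted tumor mask against ground truth pixel by pixel:
#' TP are truth pixels correctly detected, FP pixels falsely detected as
#' tumorous, FN truth pixels missed, TN background correctly left alone.
#'
#' @param pred,truth logical matrices of identical shape.
#' @return list of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  assert_mask(pred, "pred")
  assert_mask(truth, "truth", shape = dim(pred))
  structure(list(TP = sum(pred & truth),
                 FP = sum(pred & !truth),
                 FN = sum(!pred & truth),
                 TN = sum(!pred & !truth)),
            class = "confusion_counts")
}

#' Segmentation quality metrics
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), specificity TN/(TN+FP), Dice
#' score coefficient 2TP/(2TP+FP+FN) and accuracy
#' (TP+TN)/(TP+FP+FN+TN). A metric whose denominator is zero is undefined
#' and reported as `NA`, never silently as 0 or 1.
#'
#' @param c a `confusion_counts` object.
#' @return list of class `metric_set` with `precision`, `recall`,
#'   `specificity`, `dice`, `accuracy` (full precision; round for display).
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    precision = safe_div(c$TP, c$TP + c$FP),
    recall = safe_div(c$TP, c$TP + c$FN),
    specificity = safe_div(c$TN, c$TN + c$FP),
    dice = safe_div(2 * c$TP, 2 * c$TP + c$FP + c$FN),
    accuracy = safe_div(c$TP + c$TN, c$TP + c$FP + c$FN + c$TN)
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-12s %s\n", nm,
                ifelse(is.na(x[[nm]]), "undefined",
                       sprintf("%.4f", x[[nm]]))))
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}
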