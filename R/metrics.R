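# Confusion-matrix bookkeeping and the four classification performance
# metrics: purity (precision), sensitivity, specificity and accuracy,
# reported as percentages with the CTCC class as positive.

#' Confusion counts for binary CTCC/NC predictions
#'
#' @param truth,predicted equal-length vectors of `"CTCC"`/`"NC"` labels
#'   (or -1/+1).
#' @param positive label of the positive class.
#' @return object of class `bsfc_confusion` with integer fields `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = "CTCC") {
  if (length(truth) != length(predicted)) {
    stop_bsfc("truth and predicted lengths differ (%d vs %d)",
              length(truth), length(predicted))
  }
  tp <- is_positive(truth, positive)
  pp <- is_positive(predicted, positive)
  structure(
    list(TP = sum(tp & pp), FP = sum(!tp & pp),
         TN = sum(!tp & !pp), FN = sum(tp & !pp)),
    class = "bsfc_confusion"
  )
}

is_positive <- function(x, positive) {
  if (is.numeric(x)) x == 1 else as.character(x) == positive
}

#' @export
print.bsfc_confusion <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d FP=%d TN=%d FN=%d>\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

metric_or_na <- function(num, den, name) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator)", name))
    return(NA_real_)
  }
  num / den * 100
}

#' Purity (precision), percent
#'
#' TP / (TP + FP) * 100: the fraction of predicted CTCC events that are
#' true CTCCs. Zero predicted positives give `NA` with a warning.
#'
#' @param cm a [confusion_counts()] object.
#' @return percentage in `[0, 100]` or `NA`.
#' @export
purity <- function(cm) metric_or_na(cm$TP, cm$TP + cm$FP, "purity")

#' Sensitivity (recall), percent
#'
#' TP / (TP + FN) * 100.
#'
#' @inheritParams purity
#' @return percentage in `[0, 100]` or `NA`.
#' @export
sensitivity <- function(cm) metric_or_na(cm$TP, cm$TP + cm$FN,
                                         "sensitivity")

#' Specificity, percent
#'
#' TN / (TN + FP) * 100.
#'
#' @inheritParams purity
#' @return percentage in `[0, 100]` or `NA`.
#' @export
specificity <- function(cm) metric_or_na(cm$TN, cm$TN + cm$FP,
                                         "specificity")

#' Accuracy, percent
#'
#' (TP + TN) / (TP + TN + FP + FN) * 100.
#'
#' @inheritParams purity
#' @return percentage in `[0, 100]` or `NA`.
#' @export
accuracy <- function(cm) {
  metric_or_na(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN, "accuracy")
}

#' All four performance metrics at once
#'
#' @inheritParams purity
#' @return named list with `purity`, `sensitivity`, `specificity`,
#'   `accuracy` (percent; `NA` where undefined).
#' @export
performance_metrics <- function(cm) {
  list(purity = purity(cm), sensitivity = sensitivity(cm),
       specificity = specificity(cm), accuracy = accuracy(cm))
}
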