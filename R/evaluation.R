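# External-validation bookkeeping: confusion metrics and the
# prevalence-weighted accuracy identity used to check reported rate triplets.

#' Round half away from zero
#'
#' Percent rates are conventionally reported to one decimal with halves
#' rounded away from zero (72.25 -> 72.3), unlike R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion metrics for a binary classification
#'
#' Exact integer counts (TP, FP, TN, FN) and the derived sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy `(TP+TN)/n`, with
#' percent values reported to one decimal.
#'
#' @param predicted,truth equal-length label vectors.
#' @param positive the label counted as positive.
#' @return object of class `confusion_summary`: counts, rates in `[0, 1]`,
#'   and `percent` (rounded percent rates).
#' @export
confusion_metrics <- function(predicted, truth, positive) {
  if (!length(predicted)) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  p <- predicted == positive
  t <- truth == positive
  tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(predicted)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 percent = c(sensitivity = round_half_up(100 * sens),
                             specificity = round_half_up(100 * spec),
                             accuracy = round_half_up(100 * acc))),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              x$percent["sensitivity"], x$percent["specificity"],
              x$percent["accuracy"]))
  invisible(x)
}

#' Prevalence-weighted accuracy
#'
#' The identity `accuracy = (sens * n_pos + spec * n_neg) / (n_pos + n_neg)`
#' linking a sensitivity/specificity pair to the overall accuracy given the
#' class composition of the test set; agrees exactly with
#' [confusion_metrics()] when the rates come from integer counts.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param n_pos,n_neg class counts (non-negative, not both zero).
#' @return accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(sensitivity, specificity, n_pos, n_neg) {
  if (n_pos < 0 || n_neg < 0 || n_pos + n_neg == 0)
    stop("counts must be non-negative and not both zero")
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  (sensitivity * n_pos + specificity * n_neg) / (n_pos + n_neg)
}
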