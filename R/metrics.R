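# Evaluation metrics: confusion-matrix rates and rank-based ROC/AUC.

#' Binary confusion metrics
#'
#' Standard definitions, reported in percent to two decimals' worth of
#' precision. Rates with a zero denominator are `NaN` and flagged in
#' `undefined`, never silently 0.
#'
#' @param pred logical (or 0/1) predicted positives.
#' @param truth logical (or 0/1) true positives.
#' @return list of class `binary_metrics`: counts `TP`, `FP`, `FN`,
#'   `TN` and percent rates `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, plus `undefined` (character vector).
#' @export
confusion_metrics <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1)
    nr_stop("noderad_input_error", "pred and truth must have equal length >= 1")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  rate <- function(num, den) if (den == 0) NaN else 100 * num / den
  out <- list(TP = tp, FP = fp, FN = fn, TN = tn,
              accuracy = rate(tp + tn, tp + fp + fn + tn),
              sensitivity = rate(tp, tp + fn),
              specificity = rate(tn, tn + fp),
              ppv = rate(tp, tp + fp),
              npv = rate(tn, tn + fn))
  out$undefined <- names(out)[vapply(out, function(v)
    is.numeric(v) && length(v) == 1 && is.nan(v), logical(1))]
  class(out) <- "binary_metrics"
  out
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("TP %d FP %d FN %d TN %d | acc %.2f%% sens %.2f%% spec %.2f%% ppv %.2f%% npv %.2f%%\n",
              x$TP, x$FP, x$FN, x$TN, x$accuracy, x$sensitivity,
              x$specificity, x$ppv, x$npv))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC by the tie-corrected Mann-Whitney rank statistic (tied scores
#' count 1/2); the ROC is the step curve over unique score thresholds.
#'
#' @param scores numeric scores (larger = more positive).
#' @param truth logical (or 0/1) true positives; both classes required.
#' @return list with `auc` (percent) and `roc` (data.frame with
#'   `threshold`, `tpr`, `fpr`).
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    nr_stop("noderad_undefined_auc", "both classes required for AUC")
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) sum(scores[truth] >= t) / n1, 0)),
    fpr = c(0, vapply(thr, function(t) sum(scores[!truth] >= t) / n0, 0)))
  list(auc = 100 * auc, roc = roc)
}
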