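# Performance metrics: confusion-matrix statistics with case as the
# positive class and the Mann-Whitney AUC.

#' Mann-Whitney AUC
#'
#' Probability that a uniformly random case's score exceeds a uniformly
#' random control's, with ties counted one half — computed from average
#' ranks, equivalent to the exhaustive pairwise comparison.
#'
#' @param scores numeric ranking scores (higher = more case-like).
#' @param labels case/control truth.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as_class_factor(labels)
  n1 <- sum(labels == "case"); n0 <- sum(labels == "control")
  if (n1 == 0 || n0 == 0) stop_data("AUC undefined: truth contains a single class")
  r <- rank(scores)
  (sum(r[labels == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix performance report
#'
#' Accuracy, precision and recall (sensitivity) as percentages with case
#' as the positive class, plus the Mann-Whitney AUC of the ranking scores.
#'
#' @param predicted predicted case/control classes.
#' @param scores numeric case scores used for AUC.
#' @param truth true case/control labels (both classes required).
#' @return object of class `performance_report`: list with `accuracy`,
#'   `precision`, `recall` (percent), `auc`, and counts `tp fp tn fn`.
#' @export
compute_metrics <- function(predicted, scores, truth) {
  predicted <- as_class_factor(predicted)
  truth <- as_class_factor(truth)
  stopifnot(length(predicted) == length(truth), length(scores) == length(truth))
  tp <- sum(predicted == "case" & truth == "case")
  fp <- sum(predicted == "case" & truth == "control")
  tn <- sum(predicted == "control" & truth == "control")
  fn <- sum(predicted == "control" & truth == "case")
  structure(list(accuracy = 100 * (tp + tn) / length(truth),
                 precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
                 auc = auc_mann_whitney(scores, truth),
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  AUC %.3f  (TP %d FP %d TN %d FN %d)\n",
              x$accuracy, x$precision, x$recall, x$auc, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
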