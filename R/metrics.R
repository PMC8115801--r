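# Binary classification metrics; mind wandering (label 1) is the positive
# class throughout.

#' Confusion counts
#'
#' @param predicted,actual aligned 0/1 vectors.
#' @return list with `tp`, `fp`, `fn`, `tn` (positive class = 1).
#' @export
confusion_counts <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  assert_that(length(actual) > 0, "metrics", "empty input")
  list(tp = sum(predicted == 1 & actual == 1),
       fp = sum(predicted == 1 & actual == 0),
       fn = sum(predicted == 0 & actual == 1),
       tn = sum(predicted == 0 & actual == 0))
}

#' Per-actual-class-normalized confusion matrix
#'
#' Each cell is divided by its actual-class column total, so every
#' non-empty column sums to 1 (rows: predicted MW / predicted not MW;
#' columns: actual MW / actual not MW).
#'
#' @param cm confusion counts from [confusion_counts()].
#' @return 2x2 numeric matrix.
#' @export
normalize_confusion <- function(cm) {
  m <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2,
              dimnames = list(c("pred_mw", "pred_not_mw"),
                              c("actual_mw", "actual_not_mw")))
  tot <- colSums(m)
  sweep(m, 2, ifelse(tot > 0, tot, 1), "/")
}

#' Classification accuracy
#' @param cm confusion counts.
#' @return `(tp + tn) / total`.
#' @export
accuracy_score <- function(cm) {
  tot <- cm$tp + cm$fp + cm$fn + cm$tn
  assert_that(tot > 0, "metrics", "empty confusion matrix")
  (cm$tp + cm$tn) / tot
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as 0
#' when any marginal is empty.
#'
#' @param cm confusion counts.
#' @return scalar in `[-1, 1]`.
#' @export
mcc_score <- function(cm) {
  den <- (cm$tp + cm$fp) * (cm$tp + cm$fn) * (cm$tn + cm$fp) * (cm$tn + cm$fn)
  if (den == 0) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(den)
}

#' Area under the ROC curve by pair counting
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative; tied scores count 0.5. Computed from ranks
#' (Mann-Whitney), which is exactly the pairwise count.
#'
#' @param scores continuous decision scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "metrics", "both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metrics report
#'
#' @param scores continuous scores (larger = more mind-wandering-like).
#' @param predicted 0/1 predictions.
#' @param actual 0/1 truth.
#' @return an `mw_metrics` list: `accuracy`, `auc`, `mcc`, `confusion`,
#'   `confusion_normalized`, `n_test_rows`.
#' @export
metrics_report <- function(scores, predicted, actual) {
  cm <- confusion_counts(predicted, actual)
  auc <- if (length(unique(actual)) == 2) auc_score(scores, actual) else NA_real_
  structure(list(accuracy = accuracy_score(cm), auc = auc,
                 mcc = mcc_score(cm), confusion = cm,
                 confusion_normalized = normalize_confusion(cm),
                 n_test_rows = length(actual)),
            class = "mw_metrics")
}

#' @export
print.mw_metrics <- function(x, ...) {
  cat(sprintf("<mw_metrics> n=%d  accuracy %.3f  AUC %s  MCC %.3f\n",
              x$n_test_rows, x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$mcc))
  invisible(x)
}
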