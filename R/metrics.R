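#' Binary-classification metrics
#'
#' Threshold metrics (accuracy, F1, MCC at a fixed score threshold) plus the
#' threshold-free AUROC (rank statistic with midranks for ties) and AUPRC
#' (precision-recall step integration).
#'
#' @param scores Numeric prediction scores in [0, 1].
#' @param labels 0/1 vector.
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `metrics_report` with fields `accuracy`, `F1`,
#'   `MCC`, `AUROC`, `AUPRC`, `threshold`, `n`. With a single-class label
#'   vector, AUROC/AUPRC are `NA` and the threshold metrics are still
#'   computed.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n <- length(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  acc <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  structure(
    list(accuracy = acc, F1 = f1, MCC = mcc,
         AUROC = auroc(scores, labels), AUPRC = auprc(scores, labels),
         threshold = threshold, n = n),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics> n=%d acc=%.4f F1=%.4f MCC=%.4f AUROC=%s AUPRC=%s\n",
    x$n, x$accuracy, x$F1, x$MCC,
    ifelse(is.na(x$AUROC), "NA", sprintf("%.4f", x$AUROC)),
    ifelse(is.na(x$AUPRC), "NA", sprintf("%.4f", x$AUPRC))))
  invisible(x)
}

#' Area under the ROC curve via the rank-sum statistic (midranks for ties)
#' @rdname metrics_report
#' @export
auroc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve by step integration
#' @rdname metrics_report
#' @export
auprc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # collapse tied scores into single operating points
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Brute-force AUROC by concordant-pair counting (testing oracle)
#' @rdname metrics_report
#' @export
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
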