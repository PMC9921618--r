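# Classification metrics: dual-polarity F1, accuracy/precision/recall,
# confusion counts, and ROC/AUC by threshold sweep.

f1_from_counts <- function(tp, fp, fn) {
  prec_den <- tp + fp
  rec_den <- tp + fn
  prec <- if (prec_den > 0) tp / prec_den else 0
  rec <- if (rec_den > 0) tp / rec_den else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       degenerate = prec_den == 0 || rec_den == 0 || prec + rec == 0)
}

#' Compute a full metrics report for binary predictions
#'
#' F1 is reported twice, treating each label in turn as the positive
#' class (both polarities matter when classes are unbalanced: a predictor
#' trained on mostly-negative data can score well on negatives while
#' failing positives). Precision, recall and the confusion counts refer
#' to label 1 as positive. When `scores` are given, a ROC curve is built
#' by sweeping a threshold over the unique score values and the AUC is
#' integrated with the trapezoidal rule.
#'
#' Degenerate denominators (e.g. a predictor that never emits the
#' positive class) yield a metric of 0 and set the `degenerate` flag
#' rather than `NaN`.
#'
#' @param truth 0/1 vector of reference labels.
#' @param predicted 0/1 vector of predicted labels, same length.
#' @param scores optional real vector of classifier scores for label 1,
#'   used for the ROC curve.
#' @return An object of class `metrics_report`: `f1_positive`,
#'   `f1_negative`, `accuracy`, `precision`, `recall`, `tp`, `fp`, `tn`,
#'   `fn`, `degenerate`, and (with scores) `roc` (data frame `fpr`, `tpr`)
#'   and `auc`.
#' @export
compute_metrics <- function(truth, predicted, scores = NULL) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  }
  if (!all(c(truth, predicted) %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fn <- sum(truth == 1L & predicted == 0L)
  pos <- f1_from_counts(tp, fp, fn)
  neg <- f1_from_counts(tn, fn, fp)
  out <- list(f1_positive = pos$f1, f1_negative = neg$f1,
              accuracy = (tp + tn) / length(truth),
              precision = pos$precision, recall = pos$recall,
              tp = tp, fp = fp, tn = tn, fn = fn,
              degenerate = pos$degenerate || neg$degenerate)
  if (!is.null(scores)) {
    if (length(scores) != length(truth)) {
      stop("'scores' must match the label length", call. = FALSE)
    }
    roc <- roc_curve(truth, scores)
    out$roc <- roc
    out$auc <- trapezoid_auc(roc$fpr, roc$tpr)
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("F1(+)=%.3f F1(-)=%.3f acc=%.3f prec=%.3f rec=%.3f",
              x$f1_positive, x$f1_negative, x$accuracy, x$precision, x$recall))
  if (!is.null(x$auc)) cat(sprintf(" auc=%.3f", x$auc))
  cat(sprintf("  [TP=%d FP=%d TN=%d FN=%d]%s\n", x$tp, x$fp, x$tn, x$fn,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# ROC points from a threshold sweep over the unique scores, descending;
# includes the (0,0) and (1,1) endpoints.
roc_curve <- function(truth, scores) {
  np <- sum(truth == 1L)
  nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L) stop("ROC needs both classes", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1L) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0L) / nn, numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tpr[ord][-1]) / 2)
}

#' Write a metrics report as delimited text
#' @param report a [compute_metrics()] result.
#' @param path output CSV path; ROC points (if any) go to
#'   `<path>_roc.csv`.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  scalars <- report[c("f1_positive", "f1_negative", "accuracy", "precision",
                      "recall", "tp", "fp", "tn", "fn", "degenerate")]
  if (!is.null(report$auc)) scalars$auc <- report$auc
  df <- data.frame(metric = names(scalars),
                   value = vapply(scalars, as.numeric, numeric(1)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(report$roc)) {
    write.csv(report$roc, sub("(\\.[^.]*)?$", "_roc.csv", path, perl = TRUE),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
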