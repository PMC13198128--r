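# Classification and regression metrics, computed definitionally.
#
# Degenerate-case conventions (documented, NaN-free): any ratio with a zero
# denominator is 0 (precision, recall, F1, MCC); BACC averages SN and SP with
# the same convention. AUC on single-class truth is an explicit error rather
# than a silent NaN.

#' Confusion-matrix summary with derived metrics
#'
#' @param truth binary ground truth (0/1, logical, or factor with two levels)
#' @param pred predicted classes on the same coding
#' @return a `confusion_summary`: TP/FP/TN/FN counts and SN, SP, ACC, BACC,
#'   precision, recall, F1, MCC
#' @export
confusion_summary <- function(truth, pred) {
  truth <- as_binary(truth); pred <- as_binary(pred)
  stopifnot(length(truth) == length(pred), length(truth) > 0L)
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  fn <- sum(truth == 1L & pred == 0L)
  structure(c(list(TP = tp, FP = fp, TN = tn, FN = fn),
              confusion_metrics(tp, fp, tn, fn)),
            class = "confusion_summary")
}

as_binary <- function(x) {
  if (is.factor(x)) x <- as.integer(x) - 1L
  if (is.logical(x)) x <- as.integer(x)
  stopifnot(all(x %in% c(0L, 1L)))
  as.integer(x)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

confusion_metrics <- function(tp, fp, tn, fn) {
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    SN = sn, SP = sp,
    ACC = (tp + tn) / (tp + fp + tn + fn),
    BACC = (sn + sp) / 2,
    precision = prec, recall = sn,
    F1 = safe_div(2 * prec * sn, prec + sn),
    MCC = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> TP=%d FP=%d TN=%d FN=%d | ACC=%.3f BACC=%.3f F1=%.3f MCC=%.3f\n",
              x$TP, x$FP, x$TN, x$FN, x$ACC, x$BACC, x$F1, x$MCC))
  invisible(x)
}

#' Area under the ROC curve (rank-based, tie-corrected)
#'
#' Mann-Whitney statistic via midranks: `AUC = (R1 - n1 (n1 + 1) / 2) /
#' (n1 n0)` where `R1` is the midrank sum of the positive scores. Ties
#' contribute 1/2.
#'
#' @param truth binary truth
#' @param scores real-valued scores (higher = more positive)
#' @return AUC in `[0, 1]`
#' @export
auc_score <- function(truth, scores) {
  truth <- as_binary(truth)
  stopifnot(length(truth) == length(scores), all(is.finite(scores)))
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC is undefined for single-class truth (", n1, " positives, ",
         n0, " negatives)")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compute a requested set of evaluation metrics
#'
#' Classification metrics (`acc`, `bacc`, `sn`, `sp`, `precision`, `recall`,
#' `f1`, `mcc`) need `predictions`; `auc` needs `scores`; regression metrics
#' (`mse`, `spearman`, `pearson`, `r2`) treat `predictions` as real-valued.
#'
#' @param truth ground-truth vector
#' @param predictions predicted classes (classification) or values
#'   (regression)
#' @param scores real-valued scores for AUC (defaults to `predictions`)
#' @param metrics character vector of metric names (above)
#' @return tibble with columns `metric`, `value`
#' @export
compute_metrics <- function(truth, predictions = NULL, scores = NULL,
                            metrics = c("acc", "f1", "mcc")) {
  stopifnot(length(truth) > 0L)
  if (is.null(scores)) scores <- predictions
  cls <- NULL
  need_cls <- intersect(metrics, c("acc", "bacc", "sn", "sp", "precision",
                                   "recall", "f1", "mcc"))
  if (length(need_cls)) {
    stopifnot(!is.null(predictions), length(predictions) == length(truth))
    cls <- confusion_summary(truth, predictions)
  }
  val <- vapply(metrics, function(m) {
    switch(m,
      acc = cls$ACC, bacc = cls$BACC, sn = cls$SN, sp = cls$SP,
      precision = cls$precision, recall = cls$recall, f1 = cls$F1,
      mcc = cls$MCC,
      auc = auc_score(truth, scores),
      mse = mean((as.numeric(predictions) - as.numeric(truth))^2),
      spearman = stats::cor(as.numeric(truth), as.numeric(predictions),
                            method = "spearman"),
      pearson = stats::cor(as.numeric(truth), as.numeric(predictions)),
      r2 = {
        t <- as.numeric(truth); p <- as.numeric(predictions)
        1 - sum((t - p)^2) / sum((t - mean(t))^2)
      },
      stop("unknown metric '", m, "'")
    )
  }, 1)
  tibble::tibble(metric = metrics, value = unname(val))
}

#' Multi-class accuracy
#'
#' @param truth,pred integer class labels
#' @return fraction of exact matches
#' @export
multiclass_accuracy <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0L)
  mean(truth == pred)
}
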