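#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney statistic: the probability that a uniformly
#' chosen positive outranks a uniformly chosen negative, with ties counted
#' half.  Invariant to strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels of the same length.
#' @return a real in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_usage("auroc: scores and labels differ in length")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_usage("auroc is undefined when only one class is present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision without interpolation: the sum over distinct score
#' thresholds of precision at that threshold times the recall increment.
#' Tied scores are handled as a single threshold, so a constant score
#' vector yields the prevalence.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels of the same length.
#' @return a real in [0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_usage("auprc: scores and labels differ in length")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop_usage("auprc is undefined without positives")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y)
  n <- seq_along(y)
  last <- which(diff(s) != 0)            # last index of each threshold block
  last <- c(last, length(s))
  prec <- tp[last] / n[last]
  rec <- tp[last] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Confusion counts and thresholded classification metrics
#'
#' Classifies `score >= threshold` as positive and reports the confusion
#' counts together with accuracy, Matthews correlation (0 when a marginal is
#' zero), true positive/negative rates, false discovery rate (0 with no
#' predicted positives) and the error prediction rate EPR = (FP + FN)/total
#' (i.e. 1 - ACC; see [early_precision_ratio()] for the ranked-retrieval
#' alternative reading of "EPR").
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold classification threshold (default 0.5).
#' @return list with `counts` (TP, FP, TN, FN) and fields `acc`, `mcc`,
#'   `tpr`, `tnr`, `fdr`, `epr`, `threshold`.
#' @export
thresholded_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  total <- tp + fp + tn + fn
  acc <- (tp + tn) / total
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  tpr <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  tnr <- if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
  fdr <- if (tp + fp == 0L) 0 else fp / (tp + fp)
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       acc = acc, mcc = mcc, tpr = tpr, tnr = tnr, fdr = fdr,
       epr = (fp + fn) / total, threshold = threshold)
}

#' Early precision ratio
#'
#' Precision among the `top_k` highest-scoring pairs divided by the
#' prevalence of positives -- the ranked-retrieval reading of "EPR" common
#' in GRN benchmarking.  Defaults `top_k` to the number of positives.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param top_k number of top-ranked pairs to inspect.
#' @return the ratio (>= 0; 1 means no better than chance).
#' @export
early_precision_ratio <- function(scores, labels, top_k = sum(labels == 1)) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop_usage("early precision is undefined without positives")
  top_k <- check_count(top_k, "top_k", 1L)
  o <- order(scores, decreasing = TRUE)
  early <- mean(labels[o][seq_len(min(top_k, length(o)))])
  early / (n_pos / length(labels))
}

#' Full metric report for a scored edge set
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param threshold threshold for the confusion-based metrics.
#' @return object of class `metric_report`: `auroc`, `auprc`, the
#'   [thresholded_metrics()] fields, `epr_ratio` (early precision ratio) and
#'   the confusion counts.
#' @export
metric_report <- function(scores, labels, threshold = 0.5) {
  tm <- thresholded_metrics(scores, labels, threshold)
  structure(list(auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 acc = tm$acc, mcc = tm$mcc, tpr = tm$tpr, tnr = tm$tnr,
                 fdr = tm$fdr, epr = tm$epr,
                 epr_ratio = early_precision_ratio(scores, labels),
                 threshold = threshold, counts = tm$counts,
                 n = length(labels)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d  AUROC %.4f  AUPRC %.4f\n",
              x$n, x$auroc, x$auprc))
  cat(sprintf("  @%.2f: ACC %.3f  MCC %.3f  TPR %.3f  TNR %.3f  FDR %.3f  EPR %.3f\n",
              x$threshold, x$acc, x$mcc, x$tpr, x$tnr, x$fdr, x$epr))
  invisible(x)
}

metric_report_row <- function(r) {
  data.frame(auroc = r$auroc, auprc = r$auprc, acc = r$acc, mcc = r$mcc,
             tpr = r$tpr, tnr = r$tnr, fdr = r$fdr, epr = r$epr,
             epr_ratio = r$epr_ratio)
}
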