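# Fixed-recall evaluation harness: threshold calibration to a sensitivity
# target, confusion-matrix metric suite (recall, specificity, PPV, NPV,
# F1, F2), ROC/PR curves with AUC, and the recall-target sweep.

#' Calibrate a decision threshold to a recall target
#'
#' Returns the largest score value `t` such that predicting positive on
#' `score >= t` achieves recall at least `target_recall`; the achieved
#' recall is therefore the smallest recall meeting the target among all
#' cut-points (ties at the threshold are predicted positive, so the
#' achieved recall can sit slightly above the target). Always achievable:
#' at the minimum score every positive is recalled.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (both classes present).
#' @param target_recall Proportion in (0, 1].
#' @return A list of class `threshold_calibration` with `target_recall`,
#'   `achieved_recall` and `threshold`.
#' @export
calibrate_threshold <- function(scores, labels, target_recall) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            target_recall > 0, target_recall <= 1)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  pos <- scores[labels == 1L]
  cand <- sort(unique(scores), decreasing = TRUE)
  rec <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  hit <- which(rec >= target_recall)[1]  # cand is descending: first hit = largest t
  structure(list(target_recall = target_recall,
                 achieved_recall = rec[hit], threshold = cand[hit]),
            class = "threshold_calibration")
}

#' Confusion counts at a threshold
#'
#' Predict positive iff `score >= threshold`.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels of the same length.
#' @param threshold Decision threshold.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels lengths differ", call. = FALSE)
  }
  pred <- scores >= threshold
  confusion_counts(tp = sum(pred & labels == 1L),
                   fp = sum(pred & labels == 0L),
                   fn = sum(!pred & labels == 1L),
                   tn = sum(!pred & labels == 0L))
}

#' Build confusion counts directly
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_counts")
}

#' Metric suite from a confusion matrix
#'
#' recall = tp/(tp+fn), specificity = tn/(tn+fp), precision (PPV) =
#' tp/(tp+fp), NPV = tn/(tn+fn), F1 = 2PR/(P+R), and F2 = 5PR/(4P+R) (the
#' F-beta score at beta = 2, weighting recall four times as heavily as
#' precision). Precision is flagged `NA` when nothing is predicted
#' positive.
#'
#' @param counts A `confusion_counts` with at least one positive and one
#'   negative.
#' @return A list of class `metrics_report` with the counts and the six
#'   metrics as proportions.
#' @export
metrics_from_confusion <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  pos <- counts$tp + counts$fn
  neg <- counts$fp + counts$tn
  if (pos == 0 || neg == 0) {
    stop("confusion matrix must contain both classes", call. = FALSE)
  }
  recall <- counts$tp / pos
  specificity <- counts$tn / neg
  precision <- if (counts$tp + counts$fp > 0) {
    counts$tp / (counts$tp + counts$fp)
  } else NA_real_
  npv <- if (counts$tn + counts$fn > 0) {
    counts$tn / (counts$tn + counts$fn)
  } else NA_real_
  f1 <- if (is.na(precision) || precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  f2 <- if (is.na(precision) || 4 * precision + recall == 0) 0 else {
    5 * precision * recall / (4 * precision + recall)
  }
  structure(list(counts = counts, recall = recall, specificity = specificity,
                 precision = precision, npv = npv, f1 = f1, f2 = f2),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> recall %.1f%%, precision %.1f%%, specificity %.1f%%, F1 %.1f%%, F2 %.1f%%\n",
    round_half_up(100 * x$recall), round_half_up(100 * x$precision),
    round_half_up(100 * x$specificity), round_half_up(100 * x$f1),
    round_half_up(100 * x$f2)))
  invisible(x)
}

#' Display-rounded percentages of a metrics report
#'
#' Half-up rounding to one decimal, the convention of the printed clinical
#' tables this harness mirrors (e.g. 195/229 prints as 85.2).
#'
#' @param report A `metrics_report`.
#' @return Named numeric vector of percentages.
#' @export
metrics_percent <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  v <- c(recall = report$recall, precision = report$precision,
         specificity = report$specificity, npv = report$npv,
         f1 = report$f1, f2 = report$f2)
  round_half_up(100 * v, 1)
}

#' ROC and precision-recall curves with AUCs
#'
#' Threshold-sweep curves over the unique score values. ROC AUC is the
#' trapezoidal area (equal to the normalized Mann-Whitney U statistic, ties
#' counted half); PR AUC uses step interpolation (area under the
#' precision step function in recall).
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels, both classes present.
#' @return A list with `roc` (data.frame `fpr`, `tpr`, `threshold`), `pr`
#'   (data.frame `recall`, `precision`, `threshold`), `auc_roc`, `auc_pr`.
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single cut-points
  last <- rev(!duplicated(rev(s)))
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  thr <- s[last]
  P <- sum(y); N <- length(y) - P
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  rec <- tp / P
  prec <- tp / (tp + fp)
  auc_pr <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, thr)),
       pr = data.frame(recall = rec, precision = prec, threshold = thr),
       auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Sweep the operating point over recall targets
#'
#' For each target, calibrates the threshold on the supplied cohort's own
#' scores ([calibrate_threshold()]), counts the confusion matrix and
#' derives the metric suite — the protocol behind recall-threshold
#' performance tables. Calibrating on the evaluation set itself mirrors
#' the published protocol but is optimistic; pass `calibration_table` to
#' calibrate thresholds on a held-out cohort instead.
#'
#' @param model A model usable with [predict_scores()].
#' @param table The evaluation `cohort_table` (both classes present).
#' @param targets Recall targets (default `c(0.80, 0.85, 0.90, 0.95)`).
#' @param calibration_table Optional separate `cohort_table` on which
#'   thresholds are calibrated.
#' @return A data.frame with one row per target: target and achieved
#'   recall, threshold, confusion counts and metric percentages.
#' @export
recall_sweep <- function(model, table, targets = c(0.80, 0.85, 0.90, 0.95),
                         calibration_table = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  scores <- predict_scores(model, table)
  cal_scores <- scores
  cal_labels <- table$labels
  if (!is.null(calibration_table)) {
    cal_scores <- predict_scores(model, calibration_table)
    cal_labels <- calibration_table$labels
  }
  do.call(rbind, lapply(targets, function(tg) {
    cal <- calibrate_threshold(cal_scores, cal_labels, tg)
    counts <- confusion_at(scores, table$labels, cal$threshold)
    rep <- metrics_from_confusion(counts)
    pct <- metrics_percent(rep)
    data.frame(target_recall = tg, threshold = cal$threshold,
               tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
               recall = pct[["recall"]], precision = pct[["precision"]],
               specificity = pct[["specificity"]], npv = pct[["npv"]],
               f1 = pct[["f1"]], f2 = pct[["f2"]])
  }))
}
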