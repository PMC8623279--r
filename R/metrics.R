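# Confusion-matrix metrics and rank-statistic AUC for binary diagnosis.

#' Confusion counts for -1/+1 predictions
#'
#' @param pred Hard predictions in `{-1, +1}`.
#' @param truth Labels in `{-1, +1}`.
#' @return List of class `vb_confusion` with integer fields `tp`, `tn`,
#'   `fp`, `fn`; the four counts partition the samples.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L)
    stop("'pred' and 'truth' must have equal nonzero lengths")
  if (!all(pred %in% c(-1, 1)) || !all(truth %in% c(-1, 1)))
    stop("'pred' and 'truth' must be coded -1/+1")
  structure(list(tp = sum(pred == 1 & truth == 1),
                 tn = sum(pred == -1 & truth == -1),
                 fp = sum(pred == 1 & truth == -1),
                 fn = sum(pred == -1 & truth == 1)),
            class = "vb_confusion")
}

#' Area under the ROC curve by the rank statistic
#'
#' The Mann-Whitney form: the probability that a random positive scores
#' above a random negative, with ties counted one half.  Invariant to any
#' strictly increasing transform of the scores.
#'
#' @param scores Real-valued classifier scores (larger = more positive).
#' @param truth Labels in `{-1, +1}`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop("'scores' and 'truth' must have equal lengths")
  npos <- sum(truth == 1); nneg <- sum(truth == -1)
  if (npos == 0L || nneg == 0L)
    stop("undefined metric 'auc': both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Diagnosis performance report
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and -- when scores are supplied -- AUC from the rank
#' statistic over the fused real-valued scores.
#'
#' @param counts A `vb_confusion` (see [confusion()]).
#' @param scores Optional real-valued scores for AUC.
#' @param truth Labels in `{-1, +1}`, required with `scores`.
#' @return List of class `vb_metrics` with `accuracy`, `sensitivity`,
#'   `specificity`, `auc` (NA without scores) and the counts.  A zero
#'   denominator raises an error naming the undefined metric.
#' @export
metrics_report <- function(counts, scores = NULL, truth = NULL) {
  stopifnot(inherits(counts, "vb_confusion"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0L) stop("undefined metric 'accuracy': no samples")
  if (counts$tp + counts$fn == 0L)
    stop("undefined metric 'sensitivity': no positive samples")
  if (counts$tn + counts$fp == 0L)
    stop("undefined metric 'specificity': no negative samples")
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(truth)) stop("'truth' is required to compute AUC from scores")
    auc <- auc_score(scores, truth)
  }
  structure(list(accuracy = (counts$tp + counts$tn) / total,
                 sensitivity = counts$tp / (counts$tp + counts$fn),
                 specificity = counts$tn / (counts$tn + counts$fp),
                 auc = auc, counts = counts),
            class = "vb_metrics")
}

#' @export
print.vb_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f  auc %s\n",
              x$accuracy, x$sensitivity, x$specificity,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' @export
print.vb_confusion <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}
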