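# Decision-stump weak learner.  Primarily a fast, exactly reproducible
# learner for exercising and validating the boosting recursion; the 3D
# convolutional learner in cnn.R is the production weak learner.

#' Decision-stump weak learner for boosted ensembles
#'
#' Returns a trainer usable with [fit_ensemble()]: it fits a single-split
#' decision stump minimizing the *weighted* training error.  The search is
#' canonical and fully deterministic: features are scanned in column order;
#' for each feature the candidate thresholds are one value below the
#' minimum followed by the midpoints of consecutive distinct sorted values,
#' in ascending order; for each threshold polarity `+1` (predict positive
#' where value > threshold) is tried before polarity `-1`; a candidate
#' replaces the incumbent only if its weighted error is strictly smaller.
#'
#' @return A function `(x, y01, weights, seed)` (the seed is unused --
#'   stumps are deterministic) returning a list with elements `predict`
#'   (matrix -> 0/1 positive-class "probability"), `feature`, `threshold`,
#'   `polarity`, `train_error`.
#' @export
stump_trainer <- function() {
  function(x, y01, weights, seed = NULL) {
    x <- as.matrix(x)
    if (nrow(x) != length(y01) || length(y01) != length(weights))
      stop("stump trainer: inconsistent input lengths")
    y_pm <- ifelse(y01 == 1L, 1, -1)
    best <- list(err = Inf, feature = 1L, threshold = -Inf, polarity = 1)
    for (j in seq_len(ncol(x))) {
      u <- sort(unique(x[, j]))
      cand <- c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2)
      for (thr in cand) {
        base <- ifelse(x[, j] > thr, 1, -1)
        for (pol in c(1, -1)) {
          err <- sum(weights[pol * base != y_pm])
          if (err < best$err)
            best <- list(err = err, feature = j, threshold = thr, polarity = pol)
        }
      }
    }
    feature <- best$feature; threshold <- best$threshold; polarity <- best$polarity
    list(predict = function(xnew) {
           xnew <- as.matrix(xnew)
           as.numeric(polarity * ifelse(xnew[, feature] > threshold, 1, -1) == 1)
         },
         feature = feature, threshold = threshold, polarity = polarity,
         train_error = best$err)
  }
}
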