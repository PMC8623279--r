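# Independent oracles used to validate the package's implementations.
# Deliberately written as naive, loop-level code sharing nothing with the
# package's vectorized/compiled paths.

# Naive denoising oracle: mean images, difference, normalization, threshold
# mask and bounding box via explicit triple loops.
oracle_denoise <- function(group_a, group_b, alpha, use_abs = TRUE) {
  d <- dim(group_a[[1]])
  mean_of <- function(group) {
    m <- array(0, dim = d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      s <- 0
      for (v in group) s <- s + v[x, y, z]
      m[x, y, z] <- s / length(group)
    }
    m
  }
  diffim <- mean_of(group_a) - mean_of(group_b)
  vals <- if (use_abs) abs(diffim) else diffim
  mx <- -Inf
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3])
    if (vals[x, y, z] > mx) mx <- vals[x, y, z]
  if (mx == 0) stop("oracle: all-zero difference")
  mask <- array(FALSE, dim = d)
  pres <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (vals[x, y, z] / mx > alpha) {
      mask[x, y, z] <- TRUE
      pres <- rbind(pres, c(x, y, z) - 1L)
    }
  }
  if (is.null(pres)) stop("oracle: empty mask")
  lo <- apply(pres, 2, min)
  hi <- apply(pres, 2, max) + 1L
  list(normalized = vals / mx, mask = mask, preserved = pres,
       box = rbind(lo = lo, hi = hi))
}

# Independent discrete AdaBoost on decision stumps.  Implements the same
# published canonical stump rule (feature order, min-1 then ascending
# midpoints, polarity +1 before -1, strict improvement) but with its own
# vectorized search, and runs the textbook weight recursion directly.
oracle_adaboost <- function(X, y_pm, K) {
  X <- as.matrix(X)
  n <- nrow(X)
  w <- rep(1 / n, n)
  W_hist <- matrix(NA_real_, n, K)
  errs <- alphas <- numeric(K)
  votes <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    W_hist[, k] <- w
    best_err <- Inf
    best_pred <- NULL
    for (j in seq_len(ncol(X))) {
      u <- sort(unique(X[, j]))
      thrs <- c(u[1] - 1, if (length(u) > 1) head(u, -1) + diff(u) / 2)
      for (thr in thrs) for (pol in c(1, -1)) {
        pred <- pol * ifelse(X[, j] > thr, 1, -1)
        e <- sum(w * (pred != y_pm))
        if (e < best_err) { best_err <- e; best_pred <- pred }
      }
    }
    errs[k] <- best_err
    e <- min(max(best_err, 1e-10), 1 - 1e-10)
    alphas[k] <- 0.5 * log((1 - e) / e)
    votes[, k] <- best_pred
    w <- w * exp(-alphas[k] * y_pm * best_pred)
    w <- w / sum(w)
  }
  fused <- sign(votes %*% alphas)
  fused[fused == 0] <- -1
  list(weights = W_hist, errors = errs, alphas = alphas,
       fused = as.integer(fused), votes = votes)
}

# Trapezoidal ROC integration, the classical alternative to the rank form.
oracle_auc_trapezoid <- function(scores, truth) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(truth == 1); nneg <- sum(truth == -1)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & truth == 1) / npos,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & truth == -1) / nneg,
                     numeric(1)))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Small random two-group cohort of tiny volumes for oracle comparisons.
random_tiny_cohort <- function(seed) {
  set.seed(seed)
  d <- sample(2:8, 3, replace = TRUE)
  m <- sample(2:4, 1); n <- sample(2:4, 1)
  list(a = replicate(m, array(rnorm(prod(d)), dim = d), simplify = FALSE),
       b = replicate(n, array(rnorm(prod(d)), dim = d), simplify = FALSE),
       dim = d)
}
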