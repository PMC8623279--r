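# Boosting arithmetic: sample-weight initialization, weighted error, fusion
# weights, multiplicative weight updates with normalization, and adaptive
# fusion of hard votes.  The arithmetic is the classical discrete-AdaBoost
# recursion; labels are coded -1/+1 internally so that y * C(x) encodes
# agreement.

EPS_ERR <- 1e-10

#' Initialize a uniform sample-weight vector
#'
#' Round 1 of boosting starts from the uniform distribution `w_i = 1/n`.
#'
#' @param n Number of training samples (>= 1).
#' @return Numeric vector of class `vb_weights` summing to 1, with attribute
#'   `round_index = 1`.
#' @export
init_weights <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a single integer >= 1")
  n <- as.integer(n)
  structure(rep(1 / n, n), round_index = 1L, class = "vb_weights")
}

#' Weighted training error of a classifier
#'
#' The sum of the sample weights over misclassified samples.  With weights
#' summing to 1 the result lies in `[0, 1]`.
#'
#' @param w Sample weights (positive, typically summing to 1).
#' @param pred Hard predictions in `{-1, +1}`.
#' @param truth Ground-truth labels in `{-1, +1}`.
#' @return Scalar weighted error.
#' @export
weighted_error <- function(w, pred, truth) {
  if (length(w) != length(pred) || length(pred) != length(truth))
    stop("'w', 'pred' and 'truth' must have equal lengths")
  sum(as.numeric(w)[pred != truth])
}

#' Adaptive fusion weight of a classifier
#'
#' Half the natural log-odds of the weighted error:
#' `alpha = 0.5 * log((1 - e) / e)`.  Strictly decreasing in the error, zero
#' at `e = 0.5`, and antisymmetric about that point.  The error is clamped
#' to `[1e-10, 1 - 1e-10]` so perfect or fully wrong classifiers get a
#' finite weight.
#'
#' @param e Weighted error in `[0, 1]`.
#' @return Scalar fusion weight.
#' @export
fusion_weight <- function(e) {
  if (!is.numeric(e) || length(e) != 1L || is.na(e))
    stop("'e' must be a single numeric value")
  e <- min(max(e, EPS_ERR), 1 - EPS_ERR)
  0.5 * log((1 - e) / e)
}

#' Update the boosting distribution after one round
#'
#' Each weight is multiplied by `exp(-alpha * y_i * c_i)` -- shrinking
#' where the classifier agreed with the truth and growing where it erred --
#' then renormalized to sum 1 by the factor `Z_k`.
#'
#' @param w Current weights (sum 1).
#' @param alpha Fusion weight of the round's classifier.
#' @param pred Hard predictions in `{-1, +1}`.
#' @param truth Labels in `{-1, +1}`.
#' @return Updated `vb_weights` with `round_index` incremented.
#' @export
update_weights <- function(w, alpha, pred, truth) {
  if (length(w) != length(pred) || length(pred) != length(truth))
    stop("'w', 'pred' and 'truth' must have equal lengths")
  raw <- as.numeric(w) * exp(-alpha * truth * pred)
  z <- sum(raw)
  rk <- attr(w, "round_index")
  structure(raw / z,
            round_index = if (is.null(rk)) 2L else rk + 1L,
            normalizer = z, class = "vb_weights")
}

#' Hard -1/+1 label from a positive-class probability
#'
#' `+1` iff the probability exceeds 0.5; ties go to `-1`.
#'
#' @param p Probabilities in `[0, 1]`.
#' @return Integer vector in `{-1, +1}`.
#' @export
hard_label <- function(p) ifelse(p > 0.5, 1L, -1L)

n_samples <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) nrow(x) else length(x)
}

subset_samples <- function(x, idx) {
  if (is.matrix(x) || is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}

#' Fit a boosted ensemble of classifiers
#'
#' Runs `k_rounds` rounds of sample-reweighted training.  Each round trains
#' a fresh classifier under the current boosting distribution, measures its
#' weighted error on the training set, converts the error to an adaptive
#' fusion weight, and reweights the samples so the next round concentrates
#' on those just misclassified ("hard samples").  Prediction fuses the
#' classifiers' hard votes with the fusion weights.
#'
#' The two labels are mapped to the internal -1/+1 coding with the
#' alphabetically first label as +1 (so with labels `AD`/`NC`, `AD` is the
#' positive class); the mapping is stored on the model.  Rounds whose
#' weighted error reaches 0.5 or more are kept with their (non-positive)
#' fusion weight and flagged with a warning; an error of essentially 1
#' aborts with a diagnostic.
#'
#' @param x Training samples: a list of volumes or a numeric matrix with one
#'   row per sample (the `trainer` decides how to consume it).
#' @param y Labels: exactly two distinct values.
#' @param k_rounds Number of boosting rounds K (default 4, the point past
#'   which accuracy was observed to plateau).
#' @param trainer Weak-learner procedure: a function
#'   `trainer(x, y01, weights, seed)` returning a list with an element
#'   `predict`, itself a function mapping new samples to positive-class
#'   probabilities.  See [cnn_trainer()] and [stump_trainer()].
#' @param seed Master seed; round k trains with `seed + k` so every
#'   classifier gets a fresh deterministic initialization.
#' @return Object of class `boost_ensemble` with elements `classifiers`,
#'   `fusion_weights`, `errors`, `weight_history` (list of the distribution
#'   entering each round), `label_map`, `k_rounds`, `seed`.
#' @export
fit_ensemble <- function(x, y, k_rounds = 4L, trainer, seed = 1L) {
  if (!is.function(trainer)) stop("'trainer' must be a function")
  if (!is.numeric(k_rounds) || length(k_rounds) != 1L || k_rounds < 1)
    stop("'k_rounds' must be a single integer >= 1")
  k_rounds <- as.integer(k_rounds)
  n <- n_samples(x)
  y <- as.character(y)
  if (length(y) != n) stop("'y' length does not match the number of samples")
  levs <- sort(unique(y))
  if (length(levs) != 2L)
    stop("'y' must contain exactly 2 distinct labels, found ", length(levs))
  pos <- levs[1]
  y_pm <- ifelse(y == pos, 1L, -1L)
  y01 <- as.integer(y_pm == 1L)

  w <- init_weights(n)
  classifiers <- vector("list", k_rounds)
  alphas <- numeric(k_rounds)
  errors <- numeric(k_rounds)
  weight_history <- vector("list", k_rounds)
  train_hard <- matrix(NA_integer_, nrow = n, ncol = k_rounds)

  for (k in seq_len(k_rounds)) {
    weight_history[[k]] <- as.numeric(w)
    fitted <- trainer(x, y01, as.numeric(w), seed = as.integer(seed) + k)
    if (!is.list(fitted) || !is.function(fitted$predict))
      stop("trainer must return a list with a 'predict' function")
    p <- fitted$predict(x)
    hard <- hard_label(p)
    e_k <- weighted_error(w, hard, y_pm)
    if (e_k >= 1 - EPS_ERR)
      stop("round ", k, ": weighted error ", signif(e_k, 6),
           " is essentially 1; the weak learner is adversarial to the labels")
    if (e_k >= 0.5)
      warning("round ", k, ": weighted error ", signif(e_k, 4),
              " >= 0.5; classifier kept with non-positive fusion weight")
    alphas[k] <- fusion_weight(e_k)
    errors[k] <- e_k
    classifiers[[k]] <- fitted
    train_hard[, k] <- hard
    w <- update_weights(w, alphas[k], hard, y_pm)
  }

  structure(list(classifiers = classifiers, fusion_weights = alphas,
                 errors = errors, weight_history = weight_history,
                 train_hard = train_hard,
                 label_map = c(pos = pos, neg = levs[2]),
                 k_rounds = k_rounds, seed = as.integer(seed)),
            class = "boost_ensemble")
}

#' Fused prediction of a boosted ensemble
#'
#' The fused score is the fusion-weight--weighted sum of the classifiers'
#' hard votes, `f(x) = sum_k alpha_k c_k(x)`; the fused label is its sign,
#' with a score of exactly 0 resolved to `-1`.  `fusion = "soft"` replaces
#' the hard votes by `2 p_k(x) - 1`, a probability-weighted variant.
#'
#' @param model A fitted `boost_ensemble`.
#' @param x New samples in the same container type used for fitting.
#' @param fusion `"hard"` (default) or `"soft"`.
#' @return List with `score` (numeric), `label_pm` (-1/+1 integer) and
#'   `label` (original label values).
#' @export
fuse_predict <- function(model, x, fusion = c("hard", "soft")) {
  stopifnot(inherits(model, "boost_ensemble"))
  fusion <- match.arg(fusion)
  if (length(model$classifiers) == 0L) stop("empty ensemble")
  n <- n_samples(x)
  score <- numeric(n)
  for (k in seq_along(model$classifiers)) {
    p <- model$classifiers[[k]]$predict(x)
    vote <- if (fusion == "hard") as.numeric(hard_label(p)) else 2 * p - 1
    score <- score + model$fusion_weights[k] * vote
  }
  label_pm <- ifelse(score > 0, 1L, -1L)
  list(score = score, label_pm = label_pm,
       label = unname(ifelse(label_pm == 1L,
                             model$label_map["pos"], model$label_map["neg"])))
}

#' @export
predict.boost_ensemble <- function(object, newdata,
                                   type = c("score", "label", "prob"),
                                   fusion = c("hard", "soft"), ...) {
  type <- match.arg(type)
  fusion <- match.arg(fusion)
  fp <- fuse_predict(object, newdata, fusion = fusion)
  switch(type,
         score = fp$score,
         label = fp$label,
         prob = 1 / (1 + exp(-2 * fp$score)))
}

#' @export
coef.boost_ensemble <- function(object, ...) object$fusion_weights

#' @export
print.boost_ensemble <- function(x, ...) {
  cat("Boosted ensemble:", x$k_rounds, "classifiers\n")
  cat("  positive label:", x$label_map["pos"], "  negative:",
      x$label_map["neg"], "\n")
  cat("  weighted errors:", paste(signif(x$errors, 4), collapse = ", "), "\n")
  cat("  fusion weights: ", paste(signif(x$fusion_weights, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.boost_ensemble <- function(object, ...) {
  df <- data.frame(round = seq_len(object$k_rounds),
                   weighted_error = object$errors,
                   fusion_weight = object$fusion_weights)
  cat("Boosted ensemble fit\n")
  print(df, row.names = FALSE)
  invisible(df)
}
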