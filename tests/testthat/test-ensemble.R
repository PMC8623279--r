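test_that("weight initialization is uniform and sums to one", {
  expect_equal(as.numeric(init_weights(4)), rep(0.25, 4))
  expect_equal(as.numeric(init_weights(1)), 1)
  for (n in c(2, 7, 33)) expect_equal(sum(init_weights(n)), 1)
  expect_equal(attr(init_weights(5), "round_index"), 1L)
  expect_error(init_weights(0), ">= 1")
})

test_that("weighted error sums weights over misclassified samples", {
  w <- init_weights(4)
  truth <- c(1, 1, -1, -1)
  expect_equal(weighted_error(w, truth, truth), 0)
  expect_equal(weighted_error(w, c(1, -1, -1, -1), truth), 0.25)
  expect_equal(weighted_error(c(0.1, 0.2, 0.3, 0.4),
                              c(1, -1, -1, 1), c(1, 1, -1, -1)), 0.6)
  expect_error(weighted_error(w, c(1, 1), truth), "length")
})

test_that("fusion weight is the half log-odds: decreasing, antisymmetric, clamped", {
  expect_equal(fusion_weight(0.5), 0)
  expect_equal(fusion_weight(0.2), 0.5 * log(4))
  es <- seq(0.05, 0.95, by = 0.05)
  aw <- vapply(es, fusion_weight, numeric(1))
  expect_true(all(diff(aw) < 0))
  for (e in c(0.1, 0.25, 0.4))
    expect_equal(fusion_weight(e), -fusion_weight(1 - e))
  expect_true(is.finite(fusion_weight(0)))
  expect_true(is.finite(fusion_weight(1)))
  expect_gt(fusion_weight(0), fusion_weight(0.01))
})

test_that("weight update matches the multiplicative rule and conserves mass", {
  w <- init_weights(2)
  # sample 1 correct, sample 2 wrong, alpha = 0.5
  up <- update_weights(w, 0.5, pred = c(1, -1), truth = c(1, 1))
  z <- 0.5 * exp(-0.5) + 0.5 * exp(0.5)
  expect_equal(as.numeric(up), c(0.5 * exp(-0.5), 0.5 * exp(0.5)) / z)
  expect_equal(as.numeric(up), c(0.2689414, 0.7310586), tolerance = 1e-6)
  expect_equal(attr(up, "round_index"), 2L)

  # alpha = 0 leaves weights unchanged
  same <- update_weights(w, 0, pred = c(1, -1), truth = c(1, 1))
  expect_equal(as.numeric(same), as.numeric(w))

  # conservation and hard-sample growth over random instances
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    w0 <- init_weights(n)
    truth <- sample(c(-1, 1), n, replace = TRUE)
    pred <- truth
    flip <- sample(n, sample(1:max(1, n %/% 3), 1))
    pred[flip] <- -pred[flip]
    e <- weighted_error(w0, pred, truth)
    a <- fusion_weight(e)
    w1 <- update_weights(w0, a, pred, truth)
    expect_equal(sum(w1), 1, tolerance = 1e-12)
    if (e < 0.5)
      expect_true(all(as.numeric(w1)[flip] > as.numeric(w0)[flip]))
  }
})

test_that("hard labels break probability ties toward the negative class", {
  expect_equal(hard_label(c(0.49, 0.5, 0.51)), c(-1L, -1L, 1L))
})

test_that("ensemble on stumps matches the independent AdaBoost oracle per round", {
  set.seed(23)
  X <- matrix(rnorm(10), ncol = 1)
  y <- ifelse(X[, 1] + rnorm(10, sd = 0.5) > 0, "AD", "NC")
  if (length(unique(y)) < 2) y[1:2] <- c("AD", "NC")
  fit <- fit_ensemble(X, y, k_rounds = 3, trainer = stump_trainer(), seed = 1)
  orc <- oracle_adaboost(X, ifelse(y == "AD", 1, -1), 3)
  expect_equal(fit$errors, orc$errors, tolerance = 1e-12)
  expect_equal(fit$fusion_weights, orc$alphas, tolerance = 1e-12)
  for (k in 1:3)
    expect_equal(fit$weight_history[[k]], orc$weights[, k], tolerance = 1e-12)
  expect_equal(fuse_predict(fit, X)$label_pm, orc$fused)
})

test_that("K = 1 fusion reduces to the single classifier", {
  set.seed(5)
  X <- matrix(rnorm(16), ncol = 2)
  y <- rep(c("AD", "NC"), each = 4)
  fit <- fit_ensemble(X, y, k_rounds = 1, trainer = stump_trainer(), seed = 2)
  single <- fit$classifiers[[1]]$predict(X)
  expect_equal(fuse_predict(fit, X)$label_pm, hard_label(single))
  expect_length(coef(fit), 1L)
})

test_that("K = 4 stores four fusion weights and training error does not grow with K", {
  set.seed(9)
  X <- matrix(c(rnorm(12, -2), rnorm(12, 2)), ncol = 2, byrow = FALSE)
  # separable two-feature toy data
  X <- rbind(matrix(rnorm(20, -1.5), ncol = 2), matrix(rnorm(20, 1.5), ncol = 2))
  y <- rep(c("neg", "pos"), each = 10)
  fit4 <- fit_ensemble(X, y, k_rounds = 4, trainer = stump_trainer(), seed = 3)
  expect_length(fit4$fusion_weights, 4L)
  y_pm <- ifelse(y == sort(unique(y))[1], 1, -1)
  errs <- vapply(1:4, function(K) {
    sub <- fit4
    sub$classifiers <- fit4$classifiers[1:K]
    sub$fusion_weights <- fit4$fusion_weights[1:K]
    mean(fuse_predict(sub, X)$label_pm != y_pm)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("fused score combines votes and ties resolve negative", {
  fit <- structure(list(
    classifiers = list(list(predict = function(x) rep(1, n_s(x))),
                       list(predict = function(x) rep(0, n_s(x)))),
    fusion_weights = c(0.7, 0.2),
    label_map = c(pos = "AD", neg = "NC"), k_rounds = 2L),
    class = "boost_ensemble")
  n_s <- function(x) if (is.matrix(x)) nrow(x) else length(x)
  fp <- fuse_predict(fit, matrix(0, 1, 1))
  expect_equal(fp$score, 0.5)
  expect_equal(fp$label_pm, 1L)
  expect_equal(fp$label, "AD")

  fit$fusion_weights <- c(0.5, 0.5)  # votes +1, -1 -> score exactly 0
  fp0 <- fuse_predict(fit, matrix(0, 1, 1))
  expect_equal(fp0$score, 0)
  expect_equal(fp0$label_pm, -1L)

  # unanimous positive votes win regardless of positive alpha values
  fit$classifiers[[2]]$predict <- function(x) rep(1, n_s(x))
  fit$fusion_weights <- c(0.9, 0.05)
  expect_equal(fuse_predict(fit, matrix(0, 3, 1))$label_pm, rep(1L, 3))
})

test_that("degenerate rounds warn (error >= 0.5) or abort (error near 1)", {
  X <- matrix(c(-1, 1), ncol = 1)
  y <- c("a", "b")
  adversarial <- function(x, y01, weights, seed)
    list(predict = function(xnew) as.numeric(y01 == 0)[seq_len(nrow(xnew))])
  expect_error(fit_ensemble(X, y, k_rounds = 1, trainer = adversarial),
               "essentially 1")
  half <- function(x, y01, weights, seed)
    list(predict = function(xnew) rep(1, nrow(xnew)))
  expect_warning(fit_ensemble(X, y, k_rounds = 1, trainer = half), ">= 0.5")
})
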