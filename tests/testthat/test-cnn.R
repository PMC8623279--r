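test_that("shape trace at the nominal input reproduces the reference layer table", {
  arch <- architecture_config(c(192, 192, 160))
  tr <- network_shape_trace(arch)
  expect_equal(tr$output_shape, c(
    "192 x 192 x 160 x 8",
    "96 x 96 x 80 x 8",
    "96 x 96 x 80 x 16",
    "48 x 48 x 40 x 16",
    "48 x 48 x 40 x 32",
    "48 x 48 x 40 x 32",
    "24 x 24 x 20 x 32",
    "24 x 24 x 20 x 64",
    "24 x 24 x 20 x 64",
    "12 x 12 x 10 x 64",
    "12 x 12 x 10 x 64",
    "12 x 12 x 10 x 64",
    "6 x 6 x 5 x 64",
    "2048", "2048", "2"))
  expect_equal(tr$layer, 0:15)
  expect_equal(attr(tr, "flat_dim"), 6 * 6 * 5 * 64)
})

test_that("denoised input shape floor-halves to a 5 x 5 x 3 final map", {
  # independent oracle: repeated floor-halving of each extent
  halve5 <- function(e) { for (i in 1:5) e <- e %/% 2; e }
  expect_equal(vapply(c(160, 160, 120), halve5, numeric(1)), c(5, 5, 3))
  arch <- architecture_config(c(160, 160, 120))
  tr <- network_shape_trace(arch)
  expect_equal(tr$output_shape[13], "5 x 5 x 3 x 64")
  expect_equal(attr(tr, "flat_dim"), 5 * 5 * 3 * 64)
})

test_that("inputs too small for the pooling depth are a configuration error", {
  expect_error(architecture_config(c(16, 16, 16), scale_factor = 1 / 8),
               "pooling stages")
  expect_error(architecture_config(c(32, 32, 24)), "pooling stages")
})

test_that("scaled-down variants build and the forward pass is a softmax", {
  arch <- tiny_architecture(c(16, 16, 16))
  net <- build_network(arch, seed = 4)
  set.seed(4)
  x <- array(rnorm(16^3), dim = c(16, 16, 16))
  p <- predict_proba(net, x)
  expect_equal(dim(p), c(1L, 2L))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)

  # zeroed final layer gives the symmetric prediction
  nz <- net
  last <- sprintf("fc%d", length(arch$fc_widths))
  nz$params[[paste0(last, "_W")]][] <- 0
  nz$params[[paste0(last, "_b")]][] <- 0
  expect_equal(as.vector(predict_proba(nz, x)), c(0.5, 0.5))

  # batch and single-sample paths agree
  xs <- lapply(1:3, function(i) array(rnorm(16^3), dim = c(16, 16, 16)))
  pb <- predict_proba(net, xs)
  ps <- t(vapply(xs, function(v) predict_proba(net, v)[1, ], numeric(2)))
  expect_equal(unname(pb), unname(ps))
})

test_that("weighted cross-entropy matches its algebraic forms", {
  set.seed(8)
  n <- 12
  p <- runif(n, 0.05, 0.95)
  y <- sample(0:1, n, replace = TRUE)
  w <- rep(1 / n, n)
  plain_ce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(weighted_cross_entropy(p, y, w), plain_ce / n)

  # linear in each sample's weight: doubling one weight doubles its term
  w2 <- w; w2[3] <- 2 * w[3]
  delta <- weighted_cross_entropy(p, y, w2) - weighted_cross_entropy(p, y, w)
  term3 <- -w[3] * (y[3] * log(p[3]) + (1 - y[3]) * log(1 - p[3])) / n
  expect_equal(delta, term3)

  # confident correct predictions drive the loss to zero
  ph <- ifelse(y == 1, 1 - 1e-12, 1e-12)
  expect_lt(weighted_cross_entropy(ph, y, w), 1e-10)

  # a misclassified sample's loss slope grows with its weight
  g <- function(wi) {
    h <- 1e-6
    (weighted_cross_entropy(0.2 + h, 1, wi, n_total = 10) -
       weighted_cross_entropy(0.2 - h, 1, wi, n_total = 10)) / (2 * h)
  }
  expect_gt(abs(g(0.4)), abs(g(0.2)))
  expect_equal(g(0.4) / g(0.2), 2, tolerance = 1e-6)
})

test_that("training separates phantom classes and is deterministic", {
  cfg <- phantom_config(grid_shape = c(16, 16, 16), lesion_center = c(8, 8, 8),
                        lesion_radius = 3, boundary_band = 2,
                        brain_radius_fraction = 0.6, noise_sd = 0.1,
                        n_per_class = 20, seed = 31)
  co <- generate_cohort(cfg)
  y01 <- as.integer(co$labels == "AD")
  arch <- tiny_architecture(c(16, 16, 16))
  tc <- train_config(epochs = 15, learning_rate = 0.005, seed = 6)
  net <- build_network(arch, seed = 6)
  fit <- train_classifier(net, co$volumes, y01, config = tc)
  expect_true(all(is.finite(fit$history)))
  p <- predict_proba(fit, co$volumes)[, "pos"]
  expect_equal(mean((p > 0.5) == (y01 == 1)), 1.0)

  fit2 <- train_classifier(build_network(arch, seed = 6), co$volumes, y01,
                           config = tc)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)
})

test_that("shape mismatches and invalid configs are rejected", {
  arch <- tiny_architecture(c(16, 16, 16))
  net <- build_network(arch)
  expect_error(predict_proba(net, array(0, c(8, 8, 8))), "shape")
  expect_error(train_config(epochs = 0), "positive")
  expect_error(architecture_config(c(16, 16, 16), fc_widths = c(64, 3)),
               "end in 2")
})
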