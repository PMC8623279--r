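vol <- function(...) array(c(...), dim = c(length(c(...)), 1, 1))

test_that("group mean is the voxelwise average and respects group bounds", {
  v <- array(rnorm(24), dim = c(2, 3, 4))
  m <- group_mean(list(v, v, v))
  expect_equal(unclass(m), v, ignore_attr = TRUE)
  expect_equal(attr(m, "n_source"), 3L)

  m2 <- group_mean(list(vol(1, 3), vol(3, 5)))
  expect_equal(as.vector(m2), c(2, 4))

  set.seed(7)
  grp <- replicate(5, array(rnorm(27), dim = c(3, 3, 3)), simplify = FALSE)
  mg <- unclass(group_mean(grp))
  lo <- Reduce(pmin, grp); hi <- Reduce(pmax, grp)
  expect_true(all(mg >= lo - 1e-12 & mg <= hi + 1e-12))

  expect_error(group_mean(list()), "non-empty")
  expect_error(group_mean(list(vol(1, 2), array(0, c(3, 1, 1)))), "shape")
})

test_that("group difference subtracts voxelwise and is antisymmetric", {
  a <- group_mean(list(vol(2, 4)))
  b <- group_mean(list(vol(1, 1)))
  expect_equal(as.vector(group_difference(a, b)), c(1, 3))
  expect_equal(as.vector(group_difference(a, a)), c(0, 0))
  d1 <- group_difference(a, b); d2 <- group_difference(b, a)
  expect_equal(unclass(d1), -unclass(d2), ignore_attr = TRUE)
  expect_error(group_difference(a, group_mean(list(array(0, c(3, 1, 1))))),
               "shape")
})

test_that("normalization scales by the maximum and flags degenerate input", {
  d <- vol(1, 3)
  expect_equal(as.vector(normalize_difference(d)), c(1 / 3, 1))
  expect_equal(as.vector(normalize_difference(vol(-4, 2))), c(1, 0.5))
  expect_error(normalize_difference(vol(0, 0)), "degenerate")
  set.seed(1)
  for (i in 1:5) {
    x <- array(rnorm(30), dim = c(5, 3, 2))
    expect_equal(max(normalize_difference(x)), 1)
  }
})

test_that("mask thresholding is strict, populated, and monotone in alpha", {
  norm <- vol(1 / 3, 1)
  m <- build_mask(norm, alpha = 0.5)
  expect_equal(m$preserved_positions,
               matrix(c(1L, 0L, 0L), 1, dimnames = list(NULL, c("x", "y", "z"))))
  expect_equal(m$crop_box, rbind(lo = c(1L, 0L, 0L), hi = c(2L, 1L, 1L)),
               ignore_attr = TRUE)

  # alpha = 0 keeps every strictly positive voxel
  g <- array(c(0, 0.1, 0, 0.9), dim = c(4, 1, 1))
  m0 <- build_mask(g, alpha = 0)
  expect_equal(which(m0$mask), which(g > 0))

  expect_error(build_mask(norm, alpha = 1), "alpha")
  expect_error(build_mask(array(0.2, c(2, 2, 2)), alpha = 0.5), "degenerate")

  set.seed(3)
  for (i in 1:10) {
    g <- array(runif(60), dim = c(5, 4, 3))
    a1 <- runif(1, 0, 0.5); a2 <- runif(1, a1, 0.95)
    m1 <- build_mask(g, a1)
    m2 <- try(build_mask(g, a2), silent = TRUE)
    if (!inherits(m2, "try-error")) {
      expect_true(all(m2$mask <= m1$mask))  # subset
      expect_true(all(m2$crop_box["hi", ] - m2$crop_box["lo", ] <=
                        m1$crop_box["hi", ] - m1$crop_box["lo", ]))
    }
  }
})

test_that("cropping slices half-open 0-based boxes", {
  v <- vol(10, 20, 30, 40)  # 4 x 1 x 1
  box <- rbind(lo = c(1L, 0L, 0L), hi = c(3L, 1L, 1L))
  colnames(box) <- c("x", "y", "z")
  expect_equal(as.vector(apply_crop(v, box)), c(20, 30))

  full <- rbind(lo = c(0L, 0L, 0L), hi = c(4L, 1L, 1L))
  colnames(full) <- c("x", "y", "z")
  expect_equal(as.vector(apply_crop(v, full)), as.vector(v))

  bad <- rbind(lo = c(0L, 0L, 0L), hi = c(5L, 1L, 1L))
  colnames(bad) <- c("x", "y", "z")
  expect_error(apply_crop(v, bad), "bounds")
})

test_that("voxel reduction fraction matches direct arithmetic", {
  expect_equal(voxel_reduction_fraction(c(192, 192, 160), c(160, 160, 120)),
               1 - (160 * 160 * 120) / (192 * 192 * 160))
  expect_equal(voxel_reduction_fraction(c(8, 8, 8), c(8, 8, 8)), 0)
  r <- voxel_reduction_fraction(c(10, 10, 10), c(9, 10, 10))
  expect_gt(r, 0); expect_lt(r, 1)
  expect_error(voxel_reduction_fraction(c(0, 2, 2), c(0, 1, 1)), "raw shape")
})

test_that("cohort denoising crops train and test volumes identically and needs a signal", {
  cfg <- phantom_config(n_per_class = 6, noise_sd = 0.1, seed = 21)
  co <- generate_cohort(cfg)
  dn <- denoise_cohort(co$volumes[co$labels == "AD"],
                       co$volumes[co$labels == "NC"], alpha = 0.5)
  # crop box contains the planted lesion
  lespos <- which(co$truth_mask, arr.ind = TRUE)
  lo <- dn$mask$crop_box["lo", ]; hi <- dn$mask$crop_box["hi", ]
  expect_true(all(t(lespos) - 1L >= lo) && all(t(lespos) - 1L <= hi - 1L))
  # same-shape output for any volume, fit or held out
  extra <- array(rnorm(prod(cfg$grid_shape)), dim = cfg$grid_shape)
  expect_equal(dim(dn$transform(extra)), dim(dn$transform(co$volumes[[1]])))

  same <- replicate(3, array(1, c(4, 4, 4)), simplify = FALSE)
  expect_error(denoise_cohort(same, same), "degenerate")
})

test_that("module agrees voxel-for-voxel with the naive triple-loop oracle", {
  for (seed in 1:5) {
    rc <- random_tiny_cohort(seed)
    alpha <- runif(1, 0.1, 0.8)
    orc <- oracle_denoise(rc$a, rc$b, alpha)
    dn <- denoise_cohort(rc$a, rc$b, alpha = alpha)
    expect_equal(dn$mask$mask, orc$mask)
    expect_equal(unname(dn$mask$crop_box), unname(orc$box))
    expect_equal(max(abs(dn$mask$normalized - orc$normalized)), 0,
                 tolerance = 1e-12)
  }
})

test_that("voxelwise masking inside the box zeroes non-preserved voxels", {
  rc <- random_tiny_cohort(9)
  dn <- denoise_cohort(rc$a, rc$b, alpha = 0.6, voxel_mask = TRUE)
  out <- dn$transform(rc$a[[1]])
  lo <- dn$mask$crop_box["lo", ]; hi <- dn$mask$crop_box["hi", ]
  inner <- dn$mask$mask[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                        (lo[3] + 1):hi[3], drop = FALSE]
  expect_true(all(out[!inner] == 0))
  expect_equal(out[inner],
               apply_crop(rc$a[[1]], dn$mask$crop_box)[inner])
})
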