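# Synthetic phantom cohorts: two-class 3D volumes with an ellipsoidal
# "brain" foreground, a class-discriminative spherical lesion in one class,
# and an uninformative pure-noise boundary band -- the structure the
# denoising stage is designed to exploit, with a known ground truth.

#' Phantom cohort configuration
#'
#' Class `NC` volumes are the foreground ellipsoid (intensity 1 inside, 0
#' outside) plus Gaussian voxel noise; class `AD` volumes additionally add
#' `lesion_delta` inside a sphere of `lesion_radius` voxels.  A margin of
#' `boundary_band` voxels around the grid carries zero-mean noise only
#' (the foreground is clipped away from it), emulating the uninformative
#' dark boundary of real volumes.
#'
#' @param grid_shape Integer triple; default `c(32, 32, 24)`.
#' @param brain_radius_fraction Ellipsoid semi-axes as a fraction of the
#'   half-extents; default 0.65, which keeps the foreground clear of the
#'   default boundary band.
#' @param lesion_center Voxel triple (1-based array indices); default the
#'   grid center.
#' @param lesion_radius Lesion sphere radius in voxels; default 4.
#' @param lesion_delta Intensity offset added inside the lesion for class
#'   `AD`; default 1.
#' @param boundary_band Width of the pure-noise margin in voxels; must be
#'   below half the smallest extent; default 4.
#' @param noise_sd Gaussian voxel noise standard deviation; default 0.2
#'   (a 5x lesion-contrast-to-noise ratio at the defaults).
#' @param n_per_class Volumes per class; default 20.
#' @param seed Integer seed; cohorts are deterministic given it.
#' @param labels Character pair `(lesion class, control class)`; default
#'   `c("AD", "NC")`.
#' @return Object of class `vb_phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 24L),
                           brain_radius_fraction = 0.65,
                           lesion_center = NULL, lesion_radius = 4,
                           lesion_delta = 1, boundary_band = 4L,
                           noise_sd = 0.2, n_per_class = 20L, seed = 1L,
                           labels = c("AD", "NC")) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("'grid_shape' must be a triple of extents >= 4")
  if (boundary_band < 0 || boundary_band >= min(grid_shape) / 2)
    stop("'boundary_band' must be below half the smallest grid extent")
  if (is.null(lesion_center)) lesion_center <- (grid_shape + 1) / 2
  if (length(lesion_center) != 3L) stop("'lesion_center' must be a triple")
  if (lesion_radius <= 0 || lesion_delta == 0 || noise_sd < 0 ||
      n_per_class < 1)
    stop("lesion_radius must be positive, lesion_delta nonzero, noise_sd >= 0, n_per_class >= 1")
  if (length(labels) != 2L || labels[1] == labels[2])
    stop("'labels' must be two distinct values")
  cfg <- structure(list(grid_shape = grid_shape,
                        brain_radius_fraction = brain_radius_fraction,
                        lesion_center = as.numeric(lesion_center),
                        lesion_radius = as.numeric(lesion_radius),
                        lesion_delta = as.numeric(lesion_delta),
                        boundary_band = as.integer(boundary_band),
                        noise_sd = as.numeric(noise_sd),
                        n_per_class = as.integer(n_per_class),
                        seed = as.integer(seed),
                        labels = as.character(labels)),
                   class = "vb_phantom_config")
  msk <- phantom_masks(cfg)
  if (any(msk$lesion_raw & !msk$foreground))
    stop("lesion is not entirely inside the foreground ellipsoid")
  if (!any(msk$lesion)) stop("lesion contains no voxels")
  cfg
}

phantom_masks <- function(cfg) {
  d <- cfg$grid_shape
  ctr <- (d + 1) / 2
  semi <- cfg$brain_radius_fraction * d / 2
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  gx <- array(rep(ax, times = d[2] * d[3]), dim = d)
  gy <- array(rep(rep(ay, each = d[1]), times = d[3]), dim = d)
  gz <- array(rep(az, each = d[1] * d[2]), dim = d)
  fg <- ((gx - ctr[1]) / semi[1])^2 + ((gy - ctr[2]) / semi[2])^2 +
        ((gz - ctr[3]) / semi[3])^2 <= 1
  bb <- cfg$boundary_band
  if (bb > 0) {
    interior <- gx > bb & gx <= d[1] - bb &
                gy > bb & gy <= d[2] - bb &
                gz > bb & gz <= d[3] - bb
    fg <- fg & interior
  }
  lc <- cfg$lesion_center
  lesion_raw <- (gx - lc[1])^2 + (gy - lc[2])^2 + (gz - lc[3])^2 <=
    cfg$lesion_radius^2
  list(foreground = fg, lesion_raw = lesion_raw, lesion = lesion_raw & fg)
}

#' Generate a two-class phantom cohort
#'
#' Deterministic under the configured seed.  With `noise_sd = 0` the
#' difference of the class mean images is exactly `lesion_delta` inside
#' the lesion and 0 elsewhere, so the denoising stage's preserved set
#' equals the lesion voxels for any threshold in (0, 1).
#'
#' @param cfg A `vb_phantom_config`.
#' @return Object of class `vb_phantom_cohort`: list with `volumes` (list
#'   of 3D arrays, lesion class first), `labels`, `truth_mask` (logical
#'   array of lesion voxels), `config`.
#' @export
generate_cohort <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "vb_phantom_config"))
  msk <- phantom_masks(cfg)
  base <- array(0, dim = cfg$grid_shape)
  base[msk$foreground] <- 1
  lesioned <- base
  lesioned[msk$lesion] <- lesioned[msk$lesion] + cfg$lesion_delta
  set.seed(cfg$seed)
  nv <- prod(cfg$grid_shape)
  make <- function(template) {
    as_volume(template + array(stats::rnorm(nv, sd = cfg$noise_sd),
                               dim = cfg$grid_shape))
  }
  vols_pos <- replicate(cfg$n_per_class, make(lesioned), simplify = FALSE)
  vols_neg <- replicate(cfg$n_per_class, make(base), simplify = FALSE)
  volumes <- c(vols_pos, vols_neg)
  labels <- rep(cfg$labels, each = cfg$n_per_class)
  names(volumes) <- sprintf("%s_%03d", labels,
                            c(seq_len(cfg$n_per_class), seq_len(cfg$n_per_class)))
  structure(list(volumes = volumes, labels = labels,
                 truth_mask = msk$lesion, config = cfg),
            class = "vb_phantom_cohort")
}

#' Export a phantom cohort to NIfTI files plus a manifest
#'
#' @param cohort A `vb_phantom_cohort`.
#' @param dir Writable directory (created if missing).
#' @return The `vb_manifest` describing the written files (also saved as
#'   `manifest.csv` in `dir`), consumable by [load_manifest()] and
#'   [read_volume()] unchanged.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vb_phantom_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(cohort$volumes)
  paths <- file.path(dir, paste0(ids, ".nii.gz"))
  for (i in seq_along(cohort$volumes))
    write_volume(cohort$volumes[[i]], paths[i])
  mf <- as_manifest(data.frame(sample_id = ids, path = paths,
                               label = cohort$labels,
                               stringsAsFactors = FALSE))
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  mf
}

#' Jaccard overlap of two masks
#'
#' @param a,b Logical arrays of equal shape.
#' @return Intersection over union; 1 for two empty masks.
#' @export
jaccard_index <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share one shape")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' @export
print.vb_phantom_cohort <- function(x, ...) {
  cat("Phantom cohort:", length(x$volumes), "volumes of",
      paste(x$config$grid_shape, collapse = " x "), "\n")
  cat("  labels:", paste(sprintf("%s=%d", x$config$labels,
                                 x$config$n_per_class), collapse = ", "),
      " lesion voxels:", sum(x$truth_mask),
      " noise sd:", x$config$noise_sd, "\n")
  invisible(x)
}
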