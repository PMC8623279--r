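# Group-difference denoising: compare the two label groups' mean images,
# normalize the difference, threshold it to a mask, and crop every volume to
# the tight bounding box of the retained voxels.

#' Voxelwise mean image of a group
#'
#' @param group Non-empty list of same-shape 3D arrays.
#' @param label Optional label tag recorded on the result.
#' @return 3D array of class `vb_mean_image` with attributes `source_label`
#'   and `n_source`.
#' @export
group_mean <- function(group, label = NULL) {
  if (!is.list(group) || length(group) == 0L)
    stop("'group' must be a non-empty list of volumes")
  dims <- lapply(group, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      any(vapply(dims, length, integer(1)) != 3L))
    stop("every group member must be a 3D array")
  ref <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == ref), logical(1))))
    stop("group volumes do not share a single shape")
  acc <- Reduce(`+`, lapply(group, unclass))
  out <- acc / length(group)
  attr(out, "source_label") <- label
  attr(out, "n_source") <- length(group)
  class(out) <- c("vb_mean_image", class(unclass(out)))
  out
}

#' Voxelwise difference of two mean images
#'
#' The difference is antisymmetric: swapping the arguments flips its sign at
#' every voxel.
#'
#' @param a,b Same-shape 3D arrays (typically [group_mean()] outputs).
#' @return 3D array of class `vb_difference_image` with attribute
#'   `label_pair`.
#' @export
group_difference <- function(a, b) {
  if (is.null(dim(a)) || is.null(dim(b)) || !all(dim(a) == dim(b)))
    stop("mean images must share one shape")
  out <- unclass(a) - unclass(b)
  attr(out, "label_pair") <- c(attr(a, "source_label"), attr(b, "source_label"))
  attr(out, "source_label") <- NULL
  attr(out, "n_source") <- NULL
  class(out) <- c("vb_difference_image", class(unclass(out)))
  out
}

#' Normalize a difference image to [0, 1]
#'
#' By default the absolute difference is divided by its maximum, so that
#' voxels where either group exceeds the other count as discriminative and
#' the maximum of the result is exactly 1.  With `use_abs = FALSE` the raw
#' signed values are divided by the signed maximum (voxels where the second
#' group dominates then normalize to negative values and can never pass a
#' positive threshold).
#'
#' @param d A difference image (3D array).
#' @param use_abs Take `|d|` before dividing (default TRUE).
#' @return 3D array with maximum exactly 1.
#' @export
normalize_difference <- function(d, use_abs = TRUE) {
  x <- unclass(d)
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("'d' must be a 3D array")
  if (use_abs) x <- abs(x)
  mx <- max(x)
  if (mx == 0)
    stop("degenerate difference image: all voxels are zero, no scale exists")
  out <- x / mx
  attributes(out) <- list(dim = dim(x))
  out
}

#' Threshold a normalized difference image into a crop mask
#'
#' Voxels with normalized value strictly greater than `alpha` are preserved;
#' the set of preserved coordinates and its tight axis-aligned bounding box
#' define the crop.  Coordinates are 0-based; crop-box bounds are half-open
#' `[lo, hi)` per axis.
#'
#' @param normalized 3D array in `[0, 1]` (see [normalize_difference()]).
#' @param alpha Threshold in `[0, 1)`; the peak-accuracy default used
#'   throughout the package is 0.5.
#' @return An object of class `vb_crop_mask`: list with `normalized`,
#'   `alpha`, `mask` (logical 3D array), `preserved_positions` (n x 3
#'   integer matrix, 0-based), and `crop_box` (2 x 3 matrix, rows `lo`/`hi`,
#'   half-open).
#' @export
build_mask <- function(normalized, alpha = 0.5) {
  if (is.null(dim(normalized)) || length(dim(normalized)) != 3L)
    stop("'normalized' must be a 3D array")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1)
    stop("'alpha' must be a single value in [0, 1): at alpha >= 1 the mask is empty by construction")
  mask <- unclass(normalized) > alpha
  if (!any(mask))
    stop("degenerate mask: no voxel exceeds alpha = ", alpha)
  pos1 <- which(mask, arr.ind = TRUE)          # 1-based
  preserved <- pos1 - 1L                        # 0-based triples
  dimnames(preserved) <- list(NULL, c("x", "y", "z"))
  lo <- apply(pos1, 2, min) - 1L
  hi <- apply(pos1, 2, max)                     # half-open upper bound
  crop_box <- rbind(lo = as.integer(lo), hi = as.integer(hi))
  colnames(crop_box) <- c("x", "y", "z")
  structure(list(normalized = normalized, alpha = alpha, mask = mask,
                 preserved_positions = preserved, crop_box = crop_box),
            class = "vb_crop_mask")
}

#' Crop a volume to a bounding box
#'
#' @param v 3D array.
#' @param box 2 x 3 matrix with rows `lo`, `hi`: 0-based half-open bounds
#'   per axis (as produced by [build_mask()]), or a `vb_crop_mask`.
#' @return The rectangular sub-volume; its shape equals the per-axis widths
#'   `hi - lo`.
#' @export
apply_crop <- function(v, box) {
  if (inherits(box, "vb_crop_mask")) box <- box$crop_box
  if (is.null(dim(v)) || length(dim(v)) != 3L) stop("'v' must be a 3D array")
  lo <- as.integer(box["lo", ]); hi <- as.integer(box["hi", ])
  if (any(lo < 0L) || any(hi > dim(v)) || any(hi <= lo))
    stop("crop box exceeds volume bounds or is empty for shape ",
         paste(dim(v), collapse = "x"))
  out <- unclass(v)[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2], (lo[3] + 1L):hi[3],
                    drop = FALSE]
  meta <- attr(v, "spatial_meta")
  as_volume(out, spatial_meta = meta)
}

#' Fraction of voxels removed by cropping
#'
#' `1 - prod(cropped) / prod(raw)`.  Cropping a 192 x 192 x 160 grid to
#' 160 x 160 x 120 removes about 47.9% of the voxels.
#'
#' @param raw_shape,cropped_shape Integer triples of grid extents.
#' @return A value in `[0, 1]`.
#' @export
voxel_reduction_fraction <- function(raw_shape, cropped_shape) {
  raw_shape <- as.numeric(raw_shape); cropped_shape <- as.numeric(cropped_shape)
  if (length(raw_shape) != 3L || length(cropped_shape) != 3L)
    stop("shapes must be triples")
  if (any(raw_shape < 1))
    stop("raw shape must have all extents >= 1")
  if (any(cropped_shape > raw_shape) || any(cropped_shape < 0))
    stop("cropped extents must lie within the raw extents")
  1 - prod(cropped_shape) / prod(raw_shape)
}

#' Fit the denoising crop from two training groups
#'
#' Runs the full denoising pass: the two groups' mean images, their
#' difference, normalization, thresholding at `alpha`, and the tight
#' bounding box of the preserved voxel set.  The returned `transform` crops
#' any same-shape volume -- training or test -- with that one box, so the
#' crop is determined by training data only.
#'
#' @param group_a,group_b Non-empty lists of same-shape 3D arrays (the two
#'   label groups of the *training* partition).
#' @param alpha Threshold in `[0, 1)`; default 0.5.
#' @param use_abs Use the absolute difference before normalizing (default
#'   TRUE); `FALSE` gives the literal signed variant.
#' @param voxel_mask Additionally zero out voxels inside the box that are
#'   not in the preserved set (default FALSE keeps the plain rectangular
#'   crop so convolution inputs stay dense).
#' @param labels Optional character pair naming the groups.
#' @return List of class `vb_denoiser`: `mask` (a `vb_crop_mask`),
#'   `transform` (function 3D array -> cropped array), `labels`,
#'   `reduction` (fraction of voxels removed).
#' @export
denoise_cohort <- function(group_a, group_b, alpha = 0.5, use_abs = TRUE,
                           voxel_mask = FALSE, labels = NULL) {
  ma <- group_mean(group_a, label = if (!is.null(labels)) labels[1])
  mb <- group_mean(group_b, label = if (!is.null(labels)) labels[2])
  d <- group_difference(ma, mb)
  norm <- normalize_difference(d, use_abs = use_abs)
  mask <- build_mask(norm, alpha = alpha)
  box <- mask$crop_box
  inner <- NULL
  if (voxel_mask) {
    lo <- box["lo", ]; hi <- box["hi", ]
    inner <- mask$mask[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2],
                       (lo[3] + 1L):hi[3], drop = FALSE]
  }
  transform <- function(v) {
    out <- apply_crop(v, box)
    if (!is.null(inner)) out[!inner] <- 0
    out
  }
  structure(list(mask = mask, transform = transform, labels = labels,
                 reduction = voxel_reduction_fraction(dim(mask$mask),
                                                      box["hi", ] - box["lo", ])),
            class = "vb_denoiser")
}

#' @export
print.vb_crop_mask <- function(x, ...) {
  wid <- x$crop_box["hi", ] - x$crop_box["lo", ]
  cat("Crop mask (alpha =", x$alpha, ")\n")
  cat("  grid:", paste(dim(x$mask), collapse = " x "),
      " preserved voxels:", nrow(x$preserved_positions), "\n")
  cat("  crop box widths:", paste(wid, collapse = " x "), "\n")
  invisible(x)
}

#' @export
print.vb_denoiser <- function(x, ...) {
  print(x$mask)
  cat(sprintf("  voxel reduction: %.1f%%\n", 100 * x$reduction))
  invisible(x)
}
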