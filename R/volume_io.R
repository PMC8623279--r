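#' @useDynLib voxelboost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict coef median rnorm runif
#' @importFrom utils read.csv write.csv
NULL

#' Read a 3D volume from a NIfTI file
#'
#' Loads a `.nii` or `.nii.gz` file and returns it as a plain 3D numeric
#' array with the NIfTI header kept in an attribute so that a later
#' [write_volume()] can carry spatial metadata through.  Images whose stored
#' orientation differs from the canonical RAS axis convention are reoriented
#' on load, so that voxel `(a, b, c)` refers to the same anatomical position
#' in every volume of a cohort; group arithmetic in [denoise_cohort()]
#' requires that correspondence.
#'
#' @param path Path to an existing NIfTI-1 file.
#' @return A 3D numeric array of class `vb_volume` with attribute
#'   `spatial_meta` (the source image's xform, if any).
#' @seealso [write_volume()], [load_manifest()]
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path")
  if (!file.exists(path))
    stop("volume file does not exist: ", path)
  img <- RNifti::readNifti(path)
  orient <- try(RNifti::orientation(img), silent = TRUE)
  if (!inherits(orient, "try-error") && !is.na(orient) && nzchar(orient) &&
      orient != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), " dimensions: ", path)
  as_volume(arr, spatial_meta = RNifti::niftiHeader(img))
}

#' Write a 3D volume to a NIfTI file
#'
#' Voxels are stored in double precision so that a write/read round trip is
#' bit-identical.
#'
#' @param v A 3D numeric array (optionally a `vb_volume`).
#' @param path Destination path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  v <- as_volume(v)
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  arr <- unclass(v)
  attr(arr, "spatial_meta") <- NULL
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Coerce an array to a volume
#'
#' @param x A 3D numeric array.
#' @param spatial_meta Optional NIfTI header or affine record carried
#'   through I/O; not interpreted by the arithmetic.
#' @return A `vb_volume`: the same array, classed, with the metadata
#'   attached.
#' @export
as_volume <- function(x, spatial_meta = NULL) {
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("a volume must be a 3D array")
  if (any(dim(x) < 1L)) stop("all volume extents must be >= 1")
  storage.mode(x) <- "double"
  if (!is.null(spatial_meta)) attr(x, "spatial_meta") <- spatial_meta
  class(x) <- c("vb_volume", class(unclass(x)))
  x
}

#' Load a cohort manifest
#'
#' A manifest is a CSV with header columns `sample_id`, `path`, `label`
#' describing one volume per row.  For a binary diagnosis task exactly two
#' distinct labels must be present; labels are matched case-insensitively
#' and kept in their original spelling.
#'
#' @param path CSV file path.
#' @param require_binary Require exactly two distinct labels (default TRUE).
#' @return A data frame of class `vb_manifest` with columns
#'   `sample_id`, `path`, `label`, row order preserved.
#' @export
load_manifest <- function(path, require_binary = TRUE) {
  if (!file.exists(path)) stop("manifest file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "path", "label")
  if (!all(needed %in% names(df)))
    stop("manifest must have header columns sample_id, path, label")
  as_manifest(df[, needed], require_binary = require_binary)
}

#' @rdname load_manifest
#' @param df A data frame with columns `sample_id`, `path`, `label`.
#' @export
as_manifest <- function(df, require_binary = TRUE) {
  df$sample_id <- as.character(df$sample_id)
  df$path <- as.character(df$path)
  df$label <- as.character(df$label)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  labs <- unique(tolower(df$label))
  if (require_binary && length(labs) != 2L)
    stop("a binary diagnosis manifest needs exactly 2 distinct labels, found ",
         length(labs), " (", paste(labs, collapse = ", "), ")")
  rownames(df) <- NULL
  class(df) <- c("vb_manifest", "data.frame")
  df
}

#' Stratified train/test split of a cohort
#'
#' Partitions a manifest into disjoint train and test sets.  The split is
#' stratified by label: per label, `round(train_fraction * n)` samples go to
#' training.  Identical seeds give identical partitions.  The default 0.7
#' fraction reproduces the conventional 7:3 train:test ratio.
#'
#' @param manifest A `vb_manifest` (or coercible data frame).
#' @param train_fraction Fraction of each label assigned to training,
#'   in (0, 1); default 0.7.
#' @param seed Integer seed controlling the permutation.
#' @param stratified Stratify by label (default TRUE).  If FALSE a single
#'   pooled draw is taken.
#' @return A list with elements `train` and `test`, both `vb_manifest`s.
#' @export
split_cohort <- function(manifest, train_fraction = 0.7, seed = 1L,
                         stratified = TRUE) {
  manifest <- as_manifest(as.data.frame(manifest))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)")
  counts <- table(tolower(manifest$label))
  if (any(counts < 2L))
    stop("every label needs at least 2 samples to split; counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  set.seed(as.integer(seed))
  idx_train <- integer(0)
  if (stratified) {
    for (lb in sort(names(counts))) {
      rows <- which(tolower(manifest$label) == lb)
      n_tr <- round(train_fraction * length(rows))
      n_tr <- max(1L, min(length(rows) - 1L, n_tr))
      idx_train <- c(idx_train, sort(sample(rows, n_tr)))
    }
  } else {
    n_tr <- max(1L, min(nrow(manifest) - 1L,
                        round(train_fraction * nrow(manifest))))
    idx_train <- sort(sample(seq_len(nrow(manifest)), n_tr))
  }
  idx_train <- sort(idx_train)
  train <- manifest[idx_train, , drop = FALSE]
  test <- manifest[setdiff(seq_len(nrow(manifest)), idx_train), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  class(train) <- class(test) <- c("vb_manifest", "data.frame")
  list(train = train, test = test)
}

#' Read all volumes referenced by a manifest
#'
#' All volumes in one cohort must share a single shape; a mismatch is an
#' error because group arithmetic needs voxelwise correspondence.
#'
#' @param manifest A `vb_manifest`.
#' @return Named list of `vb_volume`s (names are sample ids).
#' @export
read_cohort_volumes <- function(manifest) {
  manifest <- as_manifest(as.data.frame(manifest), require_binary = FALSE)
  vols <- lapply(manifest$path, read_volume)
  names(vols) <- manifest$sample_id
  shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1L)
    stop("cohort volumes do not share a single shape: ",
         paste(unique(shapes), collapse = " vs "))
  vols
}
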