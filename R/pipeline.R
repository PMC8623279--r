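# End-to-end orchestration: stratified split, denoising fitted on the
# training partition only, boosted training, fused evaluation on the held-
# out test set, and optional persistence of every artifact.

#' Run the full diagnosis pipeline on a cohort
#'
#' Executes split -> denoise (fitted on the two training groups only) ->
#' boosted ensemble training -> fused prediction on the test partition ->
#' metrics.  Test labels are consulted only at the final metrics stage.
#' Fully deterministic given `seed`: one master seed fans out to the split
#' (`seed + 1000`) and the per-round classifier seeds (`seed + k`), all
#' recorded on the result.
#'
#' @param cohort Either a `vb_phantom_cohort`, a list with elements
#'   `volumes` (list of same-shape 3D arrays) and `labels`, or a manifest
#'   CSV path whose volumes are then read from disk.
#' @param alpha Denoising threshold in `[0, 1)`; default 0.5.
#' @param k_rounds Boosting rounds K; default 4.
#' @param train_fraction Per-label training fraction; default 0.7.
#' @param denoise Fit and apply the group-difference crop (default TRUE);
#'   FALSE trains on the raw volumes (the no-denoising ablation arm).
#' @param use_abs Absolute difference before normalization (default TRUE).
#' @param arch A `vb_architecture`, or NULL to build [tiny_architecture()]
#'   at the (possibly cropped) input shape.
#' @param config A `vb_train_config`; its seed is superseded by the
#'   per-round seeds.
#' @param trainer Optional trainer overriding the convolutional one (e.g.
#'   [stump_trainer()] on flattened volumes is not supported here --
#'   the trainer receives lists of volumes).
#' @param seed Master seed.
#' @param out_dir Optional directory: writes `metrics.json`,
#'   `predictions.csv`, `mask.nii.gz` (if denoising), and `run.json`
#'   (config and seeds record).
#' @return Object of class `vb_run`: `metrics` (a `vb_metrics`), `model`
#'   (the `boost_ensemble`), `denoiser` (or NULL), `split` (index lists),
#'   `predictions` (data frame), `seeds`, `call_config`.
#' @export
run_pipeline <- function(cohort, alpha = 0.5, k_rounds = 4L,
                         train_fraction = 0.7, denoise = TRUE,
                         use_abs = TRUE, arch = NULL,
                         config = train_config(epochs = 15L,
                                               learning_rate = 0.005),
                         trainer = NULL, seed = 1L, out_dir = NULL) {
  cohort <- as_cohort(cohort)
  volumes <- cohort$volumes
  labels <- cohort$labels
  n <- length(volumes)
  seeds <- list(master = as.integer(seed), split = as.integer(seed) + 1000L,
                rounds = as.integer(seed) + seq_len(k_rounds))

  idx <- stratified_indices(labels, train_fraction, seeds$split)
  train_vols <- volumes[idx$train]; train_lab <- labels[idx$train]
  test_vols <- volumes[idx$test]

  denoiser <- NULL
  if (denoise) {
    levs <- sort(unique(train_lab))
    denoiser <- denoise_cohort(train_vols[train_lab == levs[1]],
                               train_vols[train_lab == levs[2]],
                               alpha = alpha, use_abs = use_abs,
                               labels = levs)
    train_vols <- lapply(train_vols, denoiser$transform)
    test_vols <- lapply(test_vols, denoiser$transform)
  }

  input_shape <- dim(train_vols[[1]])
  if (is.null(trainer)) {
    if (is.null(arch)) arch <- tiny_architecture(input_shape)
    if (!all(arch$input_shape == input_shape))
      stop("architecture input shape ", paste(arch$input_shape, collapse = "x"),
           " does not match pipeline volumes ", paste(input_shape, collapse = "x"))
    trainer <- cnn_trainer(arch, config)
  }

  model <- fit_ensemble(train_vols, train_lab, k_rounds = k_rounds,
                        trainer = trainer, seed = seeds$master)

  fused <- fuse_predict(model, test_vols)
  truth_pm <- ifelse(labels[idx$test] == model$label_map["pos"], 1L, -1L)
  perf <- metrics_report(confusion(fused$label_pm, truth_pm),
                        scores = fused$score, truth = truth_pm)

  predictions <- data.frame(sample = if (!is.null(names(volumes)))
                              names(volumes)[idx$test] else idx$test,
                            truth = labels[idx$test],
                            predicted = fused$label,
                            score = fused$score,
                            stringsAsFactors = FALSE)
  run <- structure(list(metrics = perf, model = model, denoiser = denoiser,
                        split = idx, predictions = predictions, seeds = seeds,
                        call_config = list(alpha = alpha, k_rounds = k_rounds,
                                           train_fraction = train_fraction,
                                           denoise = denoise,
                                           use_abs = use_abs)),
                   class = "vb_run")
  if (!is.null(out_dir)) persist_run(run, out_dir)
  run
}

as_cohort <- function(cohort) {
  if (inherits(cohort, "vb_phantom_cohort"))
    return(list(volumes = cohort$volumes, labels = cohort$labels))
  if (is.character(cohort) && length(cohort) == 1L) {
    mf <- load_manifest(cohort)
    return(list(volumes = read_cohort_volumes(mf), labels = mf$label))
  }
  if (is.list(cohort) && !is.null(cohort$volumes) && !is.null(cohort$labels)) {
    if (length(cohort$volumes) != length(cohort$labels))
      stop("cohort volumes and labels differ in length")
    return(cohort)
  }
  stop("'cohort' must be a phantom cohort, a volumes/labels list, or a manifest path")
}

stratified_indices <- function(labels, train_fraction, seed) {
  counts <- table(labels)
  if (any(counts < 2L)) stop("every label needs at least 2 samples to split")
  set.seed(as.integer(seed))
  train <- integer(0)
  for (lb in sort(names(counts))) {
    rows <- which(labels == lb)
    n_tr <- max(1L, min(length(rows) - 1L, round(train_fraction * length(rows))))
    train <- c(train, sample(rows, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

persist_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  m <- run$metrics
  jsonlite::write_json(
    list(accuracy = m$accuracy, sensitivity = m$sensitivity,
         specificity = m$specificity, auc = m$auc,
         counts = unclass(m$counts)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(run$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  if (!is.null(run$denoiser)) {
    write_volume(as_volume(array(as.numeric(run$denoiser$mask$mask),
                                 dim = dim(run$denoiser$mask$mask))),
                 file.path(out_dir, "mask.nii.gz"))
  }
  jsonlite::write_json(
    list(config = run$call_config, seeds = run$seeds,
         fusion_weights = run$model$fusion_weights,
         errors = run$model$errors,
         label_map = as.list(run$model$label_map),
         crop_box = if (!is.null(run$denoiser))
           run$denoiser$mask$crop_box else NULL,
         reduction = if (!is.null(run$denoiser)) run$denoiser$reduction
         else NULL),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.vb_run <- function(x, ...) {
  cat("Pipeline run (alpha =", x$call_config$alpha,
      ", K =", x$call_config$k_rounds,
      ", denoise =", x$call_config$denoise, ")\n")
  cat("  train/test:", length(x$split$train), "/", length(x$split$test), "\n")
  print(x$metrics)
  invisible(x)
}

#' Accuracy grid over denoising thresholds and ensemble sizes
#'
#' One [run_pipeline()] call per `(alpha, k)` cell with shared seeds across
#' cells.  A cell whose threshold leaves no voxel above it (a degenerate
#' mask) is recorded with `NA` metrics and the error message rather than
#' aborting the grid.
#'
#' @param cohort As in [run_pipeline()].
#' @param alphas Denoising thresholds to sweep.
#' @param ks Ensemble sizes to sweep.
#' @param seed Shared master seed.
#' @param ... Further arguments passed to [run_pipeline()].
#' @return Data frame with one row per grid cell: `alpha`, `k`,
#'   `accuracy`, `sensitivity`, `specificity`, `auc`, `error` (message or
#'   NA).
#' @export
ablation_grid <- function(cohort, alphas = c(0.3, 0.5, 0.7), ks = c(1L, 4L),
                          seed = 1L, ...) {
  if (length(alphas) == 0L || length(ks) == 0L)
    stop("'alphas' and 'ks' must be nonempty")
  cohort <- as_cohort(cohort)
  rows <- list()
  for (a in alphas) for (k in ks) {
    res <- tryCatch(run_pipeline(cohort, alpha = a, k_rounds = k,
                                 seed = seed, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, k = k, accuracy = NA_real_, sensitivity = NA_real_,
        specificity = NA_real_, auc = NA_real_,
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      m <- res$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, k = k, accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, auc = m$auc, error = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
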