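# R surface over the compiled 3D convolutional classifier: architecture
# configuration and shape tracing, the weighted cross-entropy objective,
# training with Adam, and probability prediction.

#' Architecture configuration for the 3D convolutional classifier
#'
#' The default layout is the nominal diagnosis network: eight 3x3x3
#' convolutions (channels 8, 16, 32, 32, 64, 64, 64, 64), each followed by
#' batch normalization and ReLU, with five 2x2x2 max-pooling stages (after
#' convolutions 1, 2, 4, 6 and 8), then three fully connected layers
#' (2048, 2048, 2) with dropout, and a softmax output.  Spatial extents
#' follow floor division by 2 at each pooling stage; the first fully
#' connected layer's input size is computed from the actual post-pool
#' shape, so cropped inputs are handled without change.
#'
#' `scale_factor` multiplies the convolution channel counts and the hidden
#' fully connected widths (the 2-unit output is fixed), enabling desk-scale
#' variants; it does not change the depth, so small grids may instead need
#' fewer pooling stages (see [tiny_architecture()]).
#'
#' @param input_shape Integer triple of voxel extents.
#' @param conv_channels Output channels of each convolution.
#' @param pool_after 1-based indices of convolutions followed by a pooling
#'   stage.
#' @param fc_widths Fully connected widths; the last must be 2.
#' @param dropout Dropout rate on hidden fully connected layers, in
#'   `[0, 1)`; default 0.5.
#' @param scale_factor Positive multiplier on channel/hidden widths
#'   (minimum resulting width 1).
#' @return Object of class `vb_architecture`.
#' @export
architecture_config <- function(input_shape,
                                conv_channels = c(8, 16, 32, 32, 64, 64, 64, 64),
                                pool_after = c(1, 2, 4, 6, 8),
                                fc_widths = c(2048, 2048, 2),
                                dropout = 0.5, scale_factor = 1) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L))
    stop("'input_shape' must be a triple of extents >= 1")
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("'scale_factor' must be positive")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop("'dropout' must be in [0, 1)")
  conv_channels <- pmax(1L, as.integer(round(conv_channels * scale_factor)))
  nf <- length(fc_widths)
  if (nf < 1L || fc_widths[nf] != 2L)
    stop("'fc_widths' must end in 2 (two classes)")
  if (nf > 1L)
    fc_widths[-nf] <- pmax(1L, as.integer(round(fc_widths[-nf] * scale_factor)))
  pool_after <- sort(as.integer(pool_after))
  if (any(pool_after < 1L) || any(pool_after > length(conv_channels)))
    stop("'pool_after' indices must point at convolution layers")
  arch <- structure(list(input_shape = input_shape,
                         conv_channels = as.integer(conv_channels),
                         pool_after = pool_after,
                         fc_widths = as.integer(fc_widths),
                         dropout = dropout),
                    class = "vb_architecture")
  # validates that no pooling stage drops a spatial extent below 1
  trace <- network_shape_trace(arch)
  attr(arch, "flat_dim") <- attr(trace, "flat_dim")
  arch
}

#' A small architecture for modest grids
#'
#' Two convolutions (4 and 8 channels), two pooling stages, one hidden
#' fully connected layer of width 32 and a light 0.2 dropout: enough
#' capacity to separate phantom cohorts in seconds on a CPU.
#'
#' @param input_shape Integer triple of voxel extents.
#' @param ... Overrides passed to [architecture_config()].
#' @export
tiny_architecture <- function(input_shape, ...) {
  args <- list(input_shape = input_shape,
               conv_channels = c(4L, 8L), pool_after = c(1L, 2L),
               fc_widths = c(32L, 2L), dropout = 0.2)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(architecture_config, args)
}

#' Layer-by-layer shape trace of an architecture
#'
#' Returns the operation sequence with input and output shapes, one row per
#' convolution, pooling and fully connected layer -- the structural check
#' that spatial extents survive all pooling stages.  At the nominal
#' 192 x 192 x 160 input the final feature map is 6 x 6 x 5 x 64.
#'
#' @param arch A `vb_architecture`.
#' @return Data frame with columns `layer`, `operation`, `output_shape`
#'   (string `X x Y x Z x C` for spatial layers, a width for fully
#'   connected ones); attribute `flat_dim` holds the flattened feature
#'   size.  Errors if any pooling stage would reduce an extent below 1.
#' @export
network_shape_trace <- function(arch) {
  stopifnot(inherits(arch, "vb_architecture"))
  cur <- c(arch$input_shape, 1L)
  rows <- list()
  li <- 0L
  shp <- function(s) paste(s, collapse = " x ")
  for (l in seq_along(arch$conv_channels)) {
    cur[4] <- arch$conv_channels[l]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = li, operation = sprintf("conv(bn) 3 x 3 x 3 x %d", cur[4]),
      output_shape = shp(cur))
    li <- li + 1L
    if (l %in% arch$pool_after) {
      nxt <- c(cur[1:3] %/% 2L, cur[4])
      if (any(nxt[1:3] < 1L))
        stop("input ", shp(arch$input_shape), " is too small for ",
             length(arch$pool_after), " pooling stages: extent falls below 1")
      cur <- nxt
      rows[[length(rows) + 1L]] <- data.frame(
        layer = li, operation = "maxpooling 2 x 2 x 2", output_shape = shp(cur))
      li <- li + 1L
    }
  }
  flat <- prod(cur)
  for (w in arch$fc_widths) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = li, operation = sprintf("fc %d", w),
      output_shape = as.character(w))
    li <- li + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "flat_dim") <- as.integer(flat)
  out
}

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam, mini-batches of 4,
#' 50 epochs, initial learning rate `1e-4` and decay rate `1e-4`
#' (interpreted as the optimizer's weight-decay coefficient).
#'
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param decay_rate L2 weight-decay coefficient.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return Object of class `vb_train_config`.
#' @export
train_config <- function(batch_size = 4L, epochs = 50L, learning_rate = 1e-4,
                         decay_rate = 1e-4, seed = 1L) {
  vals <- c(batch_size = batch_size, epochs = epochs,
            learning_rate = learning_rate, decay_rate = decay_rate)
  if (any(vals[c("batch_size", "epochs", "learning_rate")] <= 0) ||
      decay_rate < 0)
    stop("batch_size, epochs and learning_rate must be positive; decay_rate >= 0")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, decay_rate = decay_rate,
                 seed = as.integer(seed)),
            class = "vb_train_config")
}

#' Build (initialize) a 3D convolutional classifier
#'
#' Allocates He-initialized parameters for the architecture.  The forward
#' pass of the returned model produces a softmax 2-vector summing to 1.
#'
#' @param arch A `vb_architecture`.
#' @param seed Seed for the parameter initialization.
#' @return Object of class `vb_cnn` with fields `arch`, `params`,
#'   `history` (per-epoch training loss, NULL until trained).
#' @export
build_network <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "vb_architecture"))
  params <- cpp_cnn_init(cnn_spec(arch), as.integer(seed))
  structure(list(arch = arch, params = params, history = NULL),
            class = "vb_cnn")
}

cnn_spec <- function(arch) {
  list(input_shape = arch$input_shape, conv_channels = arch$conv_channels,
       pool_after = arch$pool_after, fc_widths = arch$fc_widths,
       dropout = arch$dropout)
}

flatten_volumes <- function(volumes, input_shape) {
  if (is.matrix(volumes)) {
    if (ncol(volumes) != prod(input_shape))
      stop("flattened volume length does not match input shape ",
           paste(input_shape, collapse = "x"))
    return(volumes)
  }
  if (inherits(volumes, "vb_volume") || (is.array(volumes) && !is.list(volumes)))
    volumes <- list(volumes)
  mat <- matrix(0, nrow = length(volumes), ncol = prod(input_shape))
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (is.null(dim(v)) || !all(dim(v) == input_shape))
      stop("volume ", i, " has shape ", paste(dim(v), collapse = "x"),
           ", expected ", paste(input_shape, collapse = "x"))
    mat[i, ] <- as.vector(unclass(v))
  }
  mat
}

#' Per-sample weighted cross-entropy
#'
#' The boosting-aware objective: each sample's binary cross-entropy is
#' multiplied by its boosting weight, and the sum is divided by the full
#' training-set size `n_total`,
#' `loss = (1/N) * sum_i -w_i * (y_i log p_i + (1 - y_i) log(1 - p_i))`.
#' With uniform weights `w_i = 1/N` this equals the standard mean
#' cross-entropy divided by `N`.  Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param probs Positive-class probabilities.
#' @param truth01 Labels in `{0, 1}`.
#' @param weights Boosting weights of the same samples.
#' @param n_total Full training-set size N (defaults to `length(probs)`;
#'   pass the global N when evaluating on a mini-batch).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, truth01, weights,
                                   n_total = length(probs)) {
  if (length(probs) != length(truth01) || length(truth01) != length(weights))
    stop("'probs', 'truth01' and 'weights' must have equal lengths")
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  sum(-weights * (truth01 * log(p) + (1 - truth01) * log(1 - p))) / n_total
}

#' Train a 3D convolutional classifier
#'
#' Minimizes the weighted cross-entropy with Adam over shuffled
#' mini-batches.  Each mini-batch member carries its current boosting
#' weight without per-batch renormalization, so the epoch-summed loss is
#' exactly the global objective.  Deterministic given the configuration
#' seed.
#'
#' @param model A `vb_cnn` from [build_network()].
#' @param volumes List of 3D arrays matching the architecture's input
#'   shape (or an already-flattened matrix).
#' @param truth01 Labels in `{0, 1}`.
#' @param weights Boosting weights; default uniform `1/n`.
#' @param config A `vb_train_config`.
#' @param n_total Training-set size N in the loss denominator; defaults to
#'   the number of samples.
#' @return The trained `vb_cnn`; `history` holds per-epoch loss (finite at
#'   every epoch -- divergence aborts with a diagnostic).
#' @export
train_classifier <- function(model, volumes, truth01, weights = NULL,
                             config = train_config(), n_total = NULL) {
  stopifnot(inherits(model, "vb_cnn"), inherits(config, "vb_train_config"))
  X <- flatten_volumes(volumes, model$arch$input_shape)
  n <- nrow(X)
  truth01 <- as.integer(truth01)
  if (length(truth01) != n || !all(truth01 %in% c(0L, 1L)))
    stop("'truth01' must be 0/1 labels, one per volume")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("'weights' length must match samples")
  if (is.null(n_total)) n_total <- n
  fit <- cpp_cnn_train(cnn_spec(model$arch), model$params, X, truth01,
                       as.numeric(weights), as.integer(n_total),
                       config$epochs, config$batch_size,
                       config$learning_rate, config$decay_rate,
                       config$seed)
  model$params <- fit$params
  model$history <- as.numeric(fit$loss)
  model
}

#' Class probabilities from a 3D convolutional classifier
#'
#' Evaluation-mode forward pass (batch statistics replaced by running
#' averages, dropout off): the same volume gives the same probabilities
#' whether passed alone or in a batch.
#'
#' @param model A `vb_cnn`.
#' @param volumes A 3D array, list of arrays, or flattened matrix.
#' @return `n x 2` matrix of class probabilities (columns `neg`, `pos`),
#'   each row summing to 1.
#' @export
predict_proba <- function(model, volumes) {
  stopifnot(inherits(model, "vb_cnn"))
  X <- flatten_volumes(volumes, model$arch$input_shape)
  out <- cpp_cnn_predict(cnn_spec(model$arch), model$params, X)
  colnames(out) <- c("neg", "pos")
  out
}

#' @export
predict.vb_cnn <- function(object, newdata, ...) predict_proba(object, newdata)

#' @export
print.vb_cnn <- function(x, ...) {
  tr <- network_shape_trace(x$arch)
  cat("3D convolutional classifier\n")
  cat("  input:", paste(x$arch$input_shape, collapse = " x "),
      " layers:", nrow(tr), " flat features:", attr(tr, "flat_dim"), "\n")
  if (!is.null(x$history))
    cat("  trained", length(x$history), "epochs; final loss",
        signif(x$history[length(x$history)], 4), "\n")
  invisible(x)
}

#' Weak-learner wrapper around the 3D convolutional classifier
#'
#' Adapts the network to the [fit_ensemble()] trainer contract: every
#' boosting round builds a fresh network (seeded initialization, no warm
#' start), trains it under the round's boosting weights, and exposes a
#' positive-class probability predictor.
#'
#' @param arch A `vb_architecture`.
#' @param config A `vb_train_config`; its seed is replaced by the per-round
#'   seed supplied by [fit_ensemble()].
#' @return A trainer function `(x, y01, weights, seed)`.
#' @export
cnn_trainer <- function(arch, config = train_config()) {
  stopifnot(inherits(arch, "vb_architecture"),
            inherits(config, "vb_train_config"))
  function(x, y01, weights, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    model <- build_network(arch, seed = cfg$seed)
    model <- train_classifier(model, x, y01, weights = weights, config = cfg)
    list(predict = function(xnew) predict_proba(model, xnew)[, "pos"],
         model = model)
  }
}
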