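#' Train a voxel classifier network
#'
#' One feed-forward network per atlas: a single hidden layer of 10 sigmoid
#' neurons and a sigmoid output, trained by minibatch stochastic gradient
#' descent (backpropagation) on the log-loss. Background voxels dominate the
#' VOI, so by default the majority class is subsampled to a 1:1 ratio before
#' training (seeded). Training is deterministic given the seed. The default
#' learning rate (0.1) and epoch count (100) were chosen so the voxel
#' networks reach a sharp decision surface on VOI-sized training sets; both
#' are configuration-exposed.
#'
#' @param features numeric matrix (voxels x features), already z-scored.
#' @param labels 0/1 vector, hippocampus = 1; both classes must be present.
#' @param seed integer seed controlling init, balancing and shuffling.
#' @param hyper list overriding `hidden` (10), `lr` (0.1), `epochs` (100),
#'   `batch` (32), `balance` (TRUE).
#' @return An object of class `voxel_model` (weights, feature schema, seed).
#' @export
train_voxel_model <- function(features, labels, seed = 1, hyper = list()) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("need both hippocampus and background voxels to train")
  h <- utils::modifyList(list(hidden = 10L, lr = 0.1, epochs = 100L,
                              batch = 32L, balance = TRUE), hyper)
  set.seed(seed)
  idx <- seq_along(labels)
  if (isTRUE(h$balance)) {
    pos <- which(labels == 1); neg <- which(labels == 0)
    n <- min(length(pos), length(neg))
    idx <- c(if (length(pos) > n) sample(pos, n) else pos,
             if (length(neg) > n) sample(neg, n) else neg)
  }
  w <- nn_train_cpp(features[idx, , drop = FALSE], labels[idx],
                    h$hidden, h$lr, h$epochs, h$batch)
  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 schema = attr(features, "schema"), seed = seed, hyper = h),
            class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("<voxel_model> %d features -> %d hidden sigmoid units (seed %d)\n",
              nrow(x$W1), ncol(x$W1), x$seed))
  invisible(x)
}

#' @rdname train_voxel_model
#' @param object a `voxel_model`.
#' @param ... unused.
#' @return `predict()`: scores strictly inside `(0, 1)`, one per row.
#' @export
predict.voxel_model <- function(object, features, ...) {
  as.numeric(nn_predict_cpp(features, object$W1, object$b1, object$W2,
                            object$b2))
}

#' Cross-validated sensitivity and specificity
#'
#' Repeated stratified k-fold cross-validation of the voxel classifier:
#' sensitivity `S` is the mean true-positive rate and specificity `s` the
#' mean true-negative rate at score threshold 0.5, averaged over all folds
#' and repeats. These are the calibration inputs of the Bayesian
#' segmentation threshold.
#'
#' @inheritParams train_voxel_model
#' @param folds number of folds (default 5).
#' @param repeats number of repeated cross-validations (default 10).
#' @return Named numeric vector `c(S = ..., s = ...)`.
#' @export
cv_sensitivity_specificity <- function(features, labels, folds = 5,
                                       repeats = 10, seed = 1, hyper = list()) {
  labels <- as.numeric(labels)
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) < folds || length(neg) < folds)
    stop("too few samples per class to stratify ", folds, " folds")
  set.seed(seed)
  tpr <- tnr <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(labels))
    fold_of[sample(pos)] <- rep_len(seq_len(folds), length(pos))
    fold_of[sample(neg)] <- rep_len(seq_len(folds), length(neg))
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      model <- train_voxel_model(features[tr, , drop = FALSE], labels[tr],
                                 seed = seed * 1000L + r * 10L + f,
                                 hyper = hyper)
      sc <- predict(model, features[!tr, , drop = FALSE])
      truth <- labels[!tr]
      tpr <- c(tpr, mean(sc[truth == 1] > 0.5))
      tnr <- c(tnr, mean(sc[truth == 0] <= 0.5))
    }
  }
  c(S = mean(tpr), s = mean(tnr))
}

#' Prior probability of hippocampus membership
#'
#' The a-priori probability `P(H)` that a VOI voxel belongs to the
#' hippocampus, estimated as the mean over training scans of the fraction of
#' VOI voxels labelled hippocampus.
#'
#' @param training_masks list of binary [vol3d] masks in template space.
#' @param voi the [voi_spec].
#' @return `P(H)` in `[0, 1]`.
#' @export
estimate_prior <- function(training_masks, voi) {
  if (length(training_masks) == 0) stop("need at least one mask")
  nvoi <- prod(voi_dim(voi))
  if (nvoi == 0) stop("empty VOI")
  mean(vapply(training_masks,
              function(m) sum(extract_voi(m, voi)) / nvoi, numeric(1)))
}

#' Bayesian segmentation threshold
#'
#' The posterior probability that a voxel flagged by the classifier truly
#' belongs to the hippocampus,
#' `t = S P(H) / (S P(H) + (1 - s)(1 - P(H)))`,
#' where `S` and `s` are the cross-validated sensitivity and specificity and
#' `P(H)` the prior. `t` is strictly increasing in each of `S`, `s` and
#' `P(H)` on the open unit interval; an uninformative classifier
#' (`S = s = 0.5`) returns the prior.
#'
#' @param S sensitivity in `(0, 1]`.
#' @param s specificity in `(0, 1]`.
#' @param prior `P(H)` in `(0, 1]`.
#' @return The threshold `t` in `[0, 1]`.
#' @export
bayes_threshold <- function(S, s, prior) {
  stopifnot(S >= 0, S <= 1, s >= 0, s <= 1, prior >= 0, prior <= 1)
  num <- S * prior
  den <- num + (1 - s) * (1 - prior)
  if (den == 0) stop("degenerate threshold: S*P(H) = 0 and s = 1")
  num / den
}

#' @rdname bayes_threshold
#' @return `threshold_params()`: a `threshold_params` object bundling
#'   `S`, `s`, `prior` and the derived `t`.
#' @export
threshold_params <- function(S, s, prior) {
  structure(list(S = S, s = s, prior = prior,
                 t = bayes_threshold(S, s, prior)),
            class = "threshold_params")
}

#' @export
print.threshold_params <- function(x, ...) {
  cat(sprintf("<threshold_params> S=%.3f s=%.3f P(H)=%.3f -> t=%.3f\n",
              x$S, x$s, x$prior, x$t))
  invisible(x)
}

#' Classification score map over a VOI
#'
#' @param data VOI-shaped array (or vector, reshaped) of scores in `[0, 1]`.
#' @param voi the [voi_spec] the scores live in.
#' @return An object of class `score_map`.
#' @export
score_map <- function(data, voi) {
  d <- voi_dim(voi)
  if (!is.array(data)) data <- array(data, d)
  if (!identical(dim(data), as.integer(d))) stop("score map/VOI shape mismatch")
  if (any(data < 0 | data > 1)) stop("scores must lie in [0, 1]")
  structure(list(data = data, voi = voi), class = "score_map")
}

#' Correlation-weighted label fusion
#'
#' Voxelwise weighted mean of per-atlas score maps, with weights (the atlas
#' selection correlations) normalized to sum 1. Atlases with non-positive
#' weight are excluded; the fused score at each voxel is bounded by the
#' voxelwise min/max of the inputs (a convex combination).
#'
#' @param score_maps list of [score_map()]s sharing a VOI.
#' @param weights positive weights, one per map.
#' @return The fused [score_map()].
#' @export
fuse_scores <- function(score_maps, weights) {
  stopifnot(length(score_maps) == length(weights))
  keep <- weights > 0
  if (!any(keep)) stop("no atlas with positive weight to fuse")
  score_maps <- score_maps[keep]
  w <- weights[keep] / sum(weights[keep])
  voi <- score_maps[[1]]$voi
  for (m in score_maps)
    if (!identical(m$voi[c("lo", "hi")], voi[c("lo", "hi")]))
      stop("score maps do not share a VOI")
  acc <- Reduce(`+`, Map(function(m, wi) m$data * wi, score_maps, w))
  score_map(acc, voi)
}

#' Binarize a fused score map
#'
#' A voxel is assigned to the hippocampus when its score strictly exceeds
#' the threshold (a score exactly equal to `t` stays background).
#'
#' @param fused a [score_map()].
#' @param t threshold in `[0, 1]`.
#' @param fulldim optional full-grid dimensions: if given, the mask is
#'   embedded into a zero grid of that size.
#' @param spacing voxel spacing of the returned mask.
#' @return A binary [vol3d] (VOI-shaped, or full-grid when `fulldim` given).
#' @export
binarize <- function(fused, t, fulldim = NULL, spacing = c(1, 1, 1)) {
  stopifnot(inherits(fused, "score_map"), t >= 0, t <= 1)
  m <- (fused$data > t) + 0
  if (!is.null(fulldim)) m <- embed_voi(m, fused$voi, fulldim)
  vol3d(m, spacing = spacing)
}
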