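#' Train a multi-atlas segmentation model set
#'
#' Runs the full training side of the pipeline on a set of labelled scans:
#' intensity normalization and bias correction, data-driven template
#' construction, warping of scans and manual labels into template space,
#' automatic per-side VOI tracing from the label probability maps, feature
#' extraction with pooled z-scoring statistics, one voxel-classifier network
#' per atlas and side, and the Bayesian threshold calibrated by repeated
#' stratified cross-validation on the pooled training voxels.
#'
#' @param scans list of [vol3d] intensity scans (native space).
#' @param masks_left,masks_right lists of binary [vol3d] hippocampus masks
#'   aligned with `scans`.
#' @param config a [default_config()] list.
#' @param seed master seed; per-atlas training seeds are derived from it.
#' @param ids optional atlas ids.
#' @return An object of class `atlas_set`.
#' @export
train_atlas_set <- function(scans, masks_left, masks_right,
                            config = default_config(), seed = config$seed,
                            ids = NULL) {
  n <- length(scans)
  stopifnot(n >= 1, length(masks_left) == n, length(masks_right) == n)
  if (is.null(ids)) ids <- sprintf("atlas%02d", seq_len(n))
  pre <- lapply(scans, preprocess_scan, config = config)
  templ <- build_template(pre, iterations = config$template$iterations,
                          ids = ids, levels = config$register$levels,
                          maxit = config$register$maxit)
  d <- dim(templ$volume$data)
  warped <- Map(function(s, tf) apply_affine(s, tf, outdim = d), pre,
                templ$transforms)
  wl <- Map(function(m, tf) apply_affine(m, tf, outdim = d,
                                         method = "nearest"),
            masks_left, templ$transforms)
  wr <- Map(function(m, tf) apply_affine(m, tf, outdim = d,
                                         method = "nearest"),
            masks_right, templ$transforms)
  fc <- do.call(feature_config, config$features)
  sides <- list(
    left = train_side(warped, wl, "left", fc, config, seed),
    right = train_side(warped, wr, "right", fc, config, seed + 1L)
  )
  structure(list(template = templ, ids = ids, sides = sides, config = config,
                 seed = seed),
            class = "atlas_set")
}

preprocess_scan <- function(s, config) {
  s <- normalize_intensity(s)
  if (config$preprocess$bias_correct)
    s <- correct_bias(s, order = config$preprocess$bias_order)
  s
}

train_side <- function(warped, wmasks, side, fc, config, seed) {
  prob <- voi_probability_map(wmasks)
  voi <- define_voi(prob, padding = config$voi$padding, side = side)
  voi_vecs <- lapply(warped, extract_voi, voi = voi)
  raw <- lapply(warped, assemble_features, voi = voi, config = fc,
                scale = FALSE)
  stats <- feature_stats(do.call(rbind, raw))
  labels <- lapply(wmasks, function(m) extract_voi(m, voi))
  cls <- config$classifier
  hyper <- cls[c("hidden", "lr", "epochs", "batch")]
  models <- Map(function(x, y, i) {
    train_voxel_model(scale_features(x, stats), y, seed = seed + 100L + i,
                      hyper = hyper)
  }, raw, labels, seq_along(raw))
  # pooled, capped training sample for the threshold calibration
  X <- do.call(rbind, lapply(raw, scale_features, stats = stats))
  y <- unlist(labels)
  set.seed(seed + 7L)
  if (length(y) > cls$cv_max) {
    pick <- c(sample(which(y == 1), min(sum(y == 1), cls$cv_max %/% 2)),
              sample(which(y == 0), min(sum(y == 0), cls$cv_max %/% 2)))
    X <- X[pick, , drop = FALSE]; y <- y[pick]
  }
  Ss <- cv_sensitivity_specificity(X, y, folds = cls$cv_folds,
                                   repeats = cls$cv_repeats,
                                   seed = seed + 11L, hyper = hyper)
  prior <- estimate_prior(wmasks, voi)
  list(voi = voi, prob = prob, voi_vecs = voi_vecs, stats = stats,
       models = models, prior = prior,
       threshold = threshold_params(Ss[["S"]], Ss[["s"]], prior))
}

#' @export
print.atlas_set <- function(x, ...) {
  cat(sprintf("<atlas_set> %d atlases, template %s\n", length(x$ids),
              paste(dim(x$template$volume$data), collapse = "x")))
  for (sd in names(x$sides)) {
    s <- x$sides[[sd]]
    cat(sprintf("  %s: VOI %s voxels, P(H)=%.3f, t=%.3f\n", sd,
                prod(voi_dim(s$voi)), s$prior, s$threshold$t))
  }
  invisible(x)
}

#' Segment the hippocampi of a test scan
#'
#' The full segmentation chain: normalize and bias-correct the scan,
#' register it affinely to the template (optionally refined non-linearly),
#' then independently for each hemisphere extract the VOI intensities, rank
#' the atlases by Pearson correlation and keep the top `m` with positive
#' correlation, score every VOI voxel with each selected atlas network, fuse
#' the score maps with correlation weights, and binarize at the Bayesian
#' threshold. Volumes are measured in template space by default; set
#' `native = TRUE` to also map each mask back through the inverse affine and
#' measure it on the native grid.
#'
#' @param test a native-space [vol3d] intensity scan.
#' @param atlas_set a trained [train_atlas_set()] result.
#' @param config pipeline configuration (defaults to the one the atlas set
#'   was trained with).
#' @param native also produce native-space masks/volumes.
#' @param id subject id recorded in the result.
#' @return An object of class `segmentation_result` with per-side masks,
#'   volumes (mm^3), atlas rankings and threshold parameters, plus the
#'   recovered transform (`converged` flags a registration that hit its
#'   iteration cap; it is reported, not raised).
#' @export
segment_subject <- function(test, atlas_set, config = atlas_set$config,
                            native = FALSE, id = "subject") {
  stopifnot(is_vol3d(test), inherits(atlas_set, "atlas_set"))
  templ <- atlas_set$template$volume
  pre <- preprocess_scan(test, config)
  tf <- register_affine(pre, templ, levels = config$register$levels,
                        maxit = config$register$maxit)
  d <- dim(templ$data)
  warped <- apply_affine(pre, tf, outdim = d)
  field <- NULL
  if (isTRUE(config$register$nonlinear)) {
    field <- register_nonlinear(warped, templ,
                                smoothness = config$register$smoothness,
                                iterations = config$register$nl_iterations)
    warped <- warp_volume(warped, field = field, outdim = d)
  }
  fc <- do.call(feature_config, config$features)
  out <- list(id = id, transform = tf, converged = tf$converged)
  for (sd in names(atlas_set$sides)) {
    side <- atlas_set$sides[[sd]]
    vec <- extract_voi(warped, side$voi)
    rk <- rank_atlases(vec, side$voi_vecs, m = config$classifier$m_atlases,
                       ids = atlas_set$ids)
    use <- rk$selected & rk$r > 0
    sel <- match(rk$atlas[use], atlas_set$ids)
    feats <- assemble_features(warped, side$voi, fc, stats = side$stats)
    maps <- lapply(sel, function(i)
      score_map(predict(side$models[[i]], feats), side$voi))
    fused <- fuse_scores(maps, rk$r[use])
    mask <- binarize(fused, side$threshold$t, fulldim = d,
                     spacing = templ$spacing)
    res <- list(mask = mask, volume_mm3 = volume_of(mask), ranking = rk,
                threshold = side$threshold, fused = fused)
    if (native) {
      inv <- invert_affine(tf)
      res$mask_native <- apply_affine(mask, inv, outdim = dim(test$data),
                                      method = "nearest",
                                      spacing = test$spacing)
      res$volume_native_mm3 <- volume_of(res$mask_native)
    }
    out[[sd]] <- res
  }
  structure(out, class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s%s\n", x$id,
              if (!isTRUE(x$converged)) " (registration not converged)" else ""))
  for (sd in c("left", "right"))
    cat(sprintf("  %s: %.1f mm^3 (t = %.3f, %d atlases fused)\n", sd,
                x[[sd]]$volume_mm3, x[[sd]]$threshold$t,
                sum(x[[sd]]$ranking$selected & x[[sd]]$ranking$r > 0)))
  invisible(x)
}

#' @export
tidy.segmentation_result <- function(x, ...) {
  purrr::map_dfr(c("left", "right"), function(sd) {
    r <- x[[sd]]
    tibble::tibble(id = x$id, side = sd, volume_mm3 = r$volume_mm3,
                   threshold = r$threshold$t,
                   n_atlases = sum(r$ranking$selected & r$ranking$r > 0),
                   mean_r = mean(r$ranking$r[r$ranking$selected]),
                   converged = isTRUE(x$converged))
  })
}

# ---- (de)serialization ------------------------------------------------------

#' Save / load a trained atlas set
#'
#' The template is written as NIfTI and everything else (VOIs, feature
#' statistics, network weights, thresholds, configuration) as JSON, so a
#' trained model is a small plain-text-plus-NIfTI directory.
#'
#' @param x an `atlas_set`.
#' @param dir destination directory (created if needed).
#' @return `save_atlas_set()`: `dir` invisibly; `load_atlas_set()`: the
#'   restored `atlas_set`.
#' @export
save_atlas_set <- function(x, dir) {
  stopifnot(inherits(x, "atlas_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(x$template$volume, file.path(dir, "template.nii.gz"),
               datatype = "double")
  ser_side <- function(s) list(
    voi = list(lo = s$voi$lo, hi = s$voi$hi, side = s$voi$side,
               padding = s$voi$padding),
    voi_vecs = s$voi_vecs,
    stats = list(mean = as.list(s$stats$mean), sd = as.list(s$stats$sd),
                 keep = as.list(s$stats$keep)),
    prior = s$prior,
    threshold = unclass(s$threshold),
    models = lapply(s$models, function(m)
      list(W1 = as.vector(m$W1), dimW1 = dim(m$W1), b1 = m$b1, W2 = m$W2,
           b2 = m$b2, schema = m$schema, seed = m$seed, hyper = m$hyper))
  )
  meta <- list(ids = x$ids, seed = x$seed, config = unclass(x$config),
               provenance = x$template$provenance,
               iterations = x$template$iterations,
               sides = lapply(x$sides, ser_side))
  jsonlite::write_json(meta, file.path(dir, "atlas_set.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_atlas_set
#' @export
load_atlas_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "atlas_set.json"),
                              simplifyVector = FALSE)
  templ <- read_volume(file.path(dir, "template.nii.gz"))
  num <- function(x) as.numeric(unlist(x))
  de_side <- function(s) {
    stats <- list(mean = num(s$stats$mean), sd = num(s$stats$sd),
                  keep = as.logical(unlist(s$stats$keep)))
    names(stats$mean) <- names(s$stats$mean)
    names(stats$sd) <- names(s$stats$sd)
    models <- lapply(s$models, function(m) {
      dw <- as.integer(unlist(m$dimW1))
      structure(list(W1 = matrix(num(m$W1), dw[1], dw[2]), b1 = num(m$b1),
                     W2 = num(m$W2), b2 = as.numeric(m$b2),
                     schema = as.character(unlist(m$schema)),
                     seed = as.integer(m$seed),
                     hyper = lapply(m$hyper, function(v) unlist(v))),
                class = "voxel_model")
    })
    list(voi = voi_spec(num(s$voi$lo), num(s$voi$hi),
                        if (is.null(s$voi$side)) NA_character_ else s$voi$side,
                        as.integer(s$voi$padding)),
         voi_vecs = lapply(s$voi_vecs, num),
         stats = stats, models = models, prior = as.numeric(s$prior),
         threshold = structure(lapply(s$threshold, as.numeric),
                               class = "threshold_params"))
  }
  structure(list(template = structure(list(volume = templ,
                                           provenance = unlist(meta$provenance),
                                           iterations = as.integer(meta$iterations),
                                           transforms = NULL),
                                      class = "template"),
                 ids = as.character(unlist(meta$ids)),
                 sides = lapply(meta$sides, de_side),
                 config = restore_config(meta$config),
                 seed = as.integer(meta$seed)),
            class = "atlas_set")
}
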