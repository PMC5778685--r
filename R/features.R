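#' Integral volume (summed-volume table)
#'
#' Cumulative-sum grid supporting O(1) axis-aligned box sums through
#' 8-corner inclusion-exclusion; the workhorse behind the Haar-like
#' features.
#'
#' @param v a [vol3d] or 3D array.
#' @return An object of class `integral_volume`.
#' @export
build_integral <- function(v) {
  a <- if (is_vol3d(v)) v$data else v
  iv <- apply(a, c(2, 3), cumsum)                 # along x
  iv <- aperm(apply(iv, c(1, 3), cumsum), c(2, 1, 3))  # along y
  iv <- aperm(apply(iv, c(1, 2), cumsum), c(2, 3, 1))  # along z
  structure(list(iv = iv, dim = dim(a)), class = "integral_volume")
}

#' @rdname build_integral
#' @param iv an `integral_volume`.
#' @param lo,hi inclusive 1-based box corners.
#' @return `box_sum()`: the sum of voxels in the box.
#' @export
box_sum <- function(iv, lo, hi) {
  stopifnot(inherits(iv, "integral_volume"))
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(lo < 1L) || any(hi > iv$dim) || any(lo > hi))
    stop("box out of bounds")
  g <- function(x, y, z) {
    if (x < 1L || y < 1L || z < 1L) return(0)
    iv$iv[x, y, z]
  }
  g(hi[1], hi[2], hi[3]) -
    g(lo[1] - 1L, hi[2], hi[3]) - g(hi[1], lo[2] - 1L, hi[3]) -
    g(hi[1], hi[2], lo[3] - 1L) +
    g(lo[1] - 1L, lo[2] - 1L, hi[3]) + g(lo[1] - 1L, hi[2], lo[3] - 1L) +
    g(hi[1], lo[2] - 1L, lo[3] - 1L) -
    g(lo[1] - 1L, lo[2] - 1L, lo[3] - 1L)
}

#' Feature configuration
#'
#' Defaults for the voxel-feature stack: central moments on cubic boxes of
#' edge 3..9, Haralick texture on a 5-voxel box with 8 grey levels, and
#' Haar-like box responses on edges 3..9.
#'
#' @param moment_sizes odd cubic box edges for the moment features.
#' @param haralick_box odd box edge for the co-occurrence patch.
#' @param haralick_levels number of grey levels for quantization.
#' @param haar_sizes odd box edges for the Haar-like responses.
#' @param standardize_voi standardize each image's VOI intensities to zero
#'   mean / unit variance before computing features (default TRUE). This
#'   removes per-scan brightness and contrast differences that survive
#'   global normalization and bias correction, so the absolute-intensity
#'   features are comparable across scans.
#' @return A named list of class `feature_config`.
#' @export
feature_config <- function(moment_sizes = c(3, 5, 7, 9), haralick_box = 5,
                           haralick_levels = 8, haar_sizes = c(3, 5, 7, 9),
                           standardize_voi = TRUE) {
  check_odd <- function(x, what) {
    if (any(x %% 2 != 1)) stop(what, " must be odd")
    as.integer(x)
  }
  structure(list(moment_sizes = check_odd(moment_sizes, "moment box sizes"),
                 haralick_box = check_odd(haralick_box, "haralick box"),
                 haralick_levels = as.integer(haralick_levels),
                 haar_sizes = check_odd(haar_sizes, "haar sizes"),
                 standardize_voi = isTRUE(standardize_voi)),
            class = "feature_config")
}

as_subvolume <- function(v) {
  if (is_vol3d(v)) v$data else if (is.array(v) && length(dim(v)) == 3) v
  else stop("expected a vol3d or 3D array")
}

#' Central-moment voxel features
#'
#' For each cubic box edge, the mean, population standard deviation,
#' skewness (standardized 3rd moment) and excess kurtosis (standardized 4th
#' moment minus 3) of the box centred on the voxel. Boxes crossing the
#' volume boundary use mirror padding. Zero-variance boxes return 0 for the
#' standardized moments.
#'
#' @param v a [vol3d] or 3D array (typically the VOI subvolume).
#' @param voxel optional 1-based `(x, y, z)` index; if `NULL`, features for
#'   every voxel are returned in raster order.
#' @param sizes odd box edges (default `c(3, 5, 7, 9)`).
#' @return A matrix (voxels x features) with named columns
#'   `mom_{mean,sd,skew,kurt}_{size}`; a single row if `voxel` is given.
#' @export
moment_features <- function(v, voxel = NULL, sizes = c(3, 5, 7, 9)) {
  a <- as_subvolume(v)
  if (any(sizes %% 2 != 1)) stop("box sizes must be odd")
  m <- moment_features_cpp(a, dim(a), as.integer(sizes))
  colnames(m) <- as.vector(vapply(
    sizes, function(s) sprintf("mom_%s_%d", c("mean", "sd", "skew", "kurt"), s),
    character(4)))
  pick_voxel(m, voxel, dim(a))
}

pick_voxel <- function(m, voxel, d) {
  if (is.null(voxel)) return(m)
  voxel <- as.integer(voxel)
  if (any(voxel < 1L) || any(voxel > d)) stop("voxel outside the volume")
  k <- voxel[1] + d[1] * ((voxel[2] - 1L) + d[2] * (voxel[3] - 1L))
  m[k, , drop = FALSE]
}

quantize_levels <- function(a, levels, rng = range(a)) {
  if (rng[2] == rng[1]) return(array(0L, dim(a)))
  q <- as.integer(pmin(floor((a - rng[1]) / (rng[2] - rng[1]) * levels),
                       levels - 1L))
  array(q, dim(a))
}

#' Haralick texture voxel features
#'
#' The local patch (cubic, clipped at the volume boundary) is scanned over
#' the 13 unique 3D unit offsets; one symmetric grey-level co-occurrence
#' matrix per offset yields energy, contrast, correlation, homogeneity
#' (inverse difference moment) and entropy (nats), averaged over offsets.
#' Quantization uses equal-width bins over the full volume range (not
#' per-patch), so GLCMs are comparable across voxels.
#'
#' @inheritParams moment_features
#' @param box odd patch edge (default 5).
#' @param levels grey levels (default 8, minimum 2).
#' @return A matrix (voxels x 5) with columns
#'   `har_{energy,contrast,corr,homog,entropy}`.
#' @export
haralick_features <- function(v, voxel = NULL, box = 5, levels = 8) {
  a <- as_subvolume(v)
  if (box %% 2 != 1) stop("box must be odd")
  if (levels < 2) stop("need at least 2 grey levels")
  q <- quantize_levels(a, levels)
  m <- haralick_features_cpp(q, dim(a), as.integer(box), as.integer(levels))
  colnames(m) <- paste0("har_", c("energy", "contrast", "corr", "homog",
                                  "entropy"))
  pick_voxel(m, voxel, dim(a))
}

#' Haar-like voxel features
#'
#' Per box edge, four box-filter responses computed from an integral
#' volume: the differences of half-box means along x (left-right), y
#' (anterior-posterior) and z (superior-inferior), and a centre-minus-
#' surround contrast. Boxes crossing the boundary are clipped and every part
#' is normalized by its actual voxel count.
#'
#' @inheritParams moment_features
#' @return A matrix (voxels x 4 * length(sizes)) with columns
#'   `haar_{x,y,z,cs}_{size}`.
#' @export
haar_features <- function(v, voxel = NULL, sizes = c(3, 5, 7, 9)) {
  a <- as_subvolume(v)
  if (any(sizes %% 2 != 1)) stop("box sizes must be odd")
  m <- haar_features_cpp(a, dim(a), as.integer(sizes))
  colnames(m) <- as.vector(vapply(
    sizes, function(s) sprintf("haar_%s_%d", c("x", "y", "z", "cs"), s),
    character(4)))
  pick_voxel(m, voxel, dim(a))
}

#' Assemble the per-voxel feature matrix of a VOI
#'
#' One row per VOI voxel in [extract_voi()] raster order; columns stack the
#' moment, Haralick and Haar features of the configuration. Columns are
#' z-scored: when `stats` is `NULL` the matrix's own column statistics are
#' used (and returned, so they can be frozen on training data); passing the
#' training `stats` applies them unchanged to new scans. Zero-variance
#' columns are dropped with a warning and recorded in the statistics.
#'
#' @param v a [vol3d] in template space.
#' @param voi a [voi_spec].
#' @param config a [feature_config()].
#' @param stats optional statistics from a previous (training) call.
#' @param scale if `FALSE`, return raw features (used internally to pool
#'   training statistics across atlases).
#' @return A numeric matrix with attributes `schema` (kept column names) and
#'   `stats` (list `mean`, `sd`, `keep`).
#' @export
assemble_features <- function(v, voi, config = feature_config(), stats = NULL,
                              scale = TRUE) {
  sub <- voi_subvolume(v, voi)
  if (isTRUE(config$standardize_voi) && stats::sd(sub) > 0)
    sub <- (sub - mean(sub)) / stats::sd(sub)
  m <- cbind(moment_features(sub, sizes = config$moment_sizes),
             haralick_features(sub, box = config$haralick_box,
                               levels = config$haralick_levels),
             haar_features(sub, sizes = config$haar_sizes))
  if (!scale) return(m)
  if (is.null(stats)) stats <- feature_stats(m)
  scale_features(m, stats)
}

#' @rdname assemble_features
#' @param m raw feature matrix (or `rbind` of several).
#' @export
feature_stats <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  keep <- sdv > 0
  if (any(!keep))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  list(mean = mu, sd = sdv, keep = keep)
}

#' @rdname assemble_features
#' @export
scale_features <- function(m, stats) {
  keep <- stats$keep
  out <- sweep(sweep(m[, keep, drop = FALSE], 2, stats$mean[keep], "-"),
               2, stats$sd[keep], "/")
  attr(out, "schema") <- colnames(m)[keep]
  attr(out, "stats") <- stats
  out
}
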