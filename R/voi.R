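#' Peri-hippocampal volume of interest
#'
#' A `voi_spec` is an axis-aligned sub-box of the template grid given by
#' inclusive 1-based start/end indices per axis. All voxel-level learning
#' happens inside the VOI, which is traced automatically so that the
#' hippocampi of all warped training scans are contained within it.
#'
#' @param lo,hi integer length-3 inclusive bounds (1-based), `lo <= hi`.
#' @param side `"left"`, `"right"` or `NA`.
#' @param padding padding (voxels) recorded for provenance.
#' @return An object of class `voi_spec`.
#' @export
voi_spec <- function(lo, hi, side = NA_character_, padding = 0L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo < 1L) || any(lo > hi))
    stop("VOI bounds must satisfy 1 <= lo <= hi on every axis")
  structure(list(lo = lo, hi = hi, side = side, padding = as.integer(padding)),
            class = "voi_spec")
}

#' @export
print.voi_spec <- function(x, ...) {
  cat(sprintf("<voi_spec%s> x:[%d,%d] y:[%d,%d] z:[%d,%d] (%d voxels)\n",
              if (is.na(x$side)) "" else paste0(" ", x$side),
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3],
              prod(x$hi - x$lo + 1L)))
  invisible(x)
}

voi_dim <- function(voi) voi$hi - voi$lo + 1L

#' Voxelwise label probability map
#'
#' The voxelwise mean of a set of warped binary masks: each voxel gets the
#' fraction of training scans whose hippocampus covers it. This probability
#' map drives the automatic VOI tracing.
#'
#' @param warped_masks list of binary [vol3d] masks on a common grid.
#' @return A [vol3d] of probabilities in `[0, 1]`.
#' @export
voi_probability_map <- function(warped_masks) {
  if (length(warped_masks) == 0) stop("need at least one mask")
  stopifnot(all(vapply(warped_masks, is_vol3d, TRUE)))
  d <- dim(warped_masks[[1]]$data)
  for (m in warped_masks) {
    if (!identical(dim(m$data), d)) stop("mask shapes differ")
    check_binary(m)
  }
  avg <- Reduce(`+`, lapply(warped_masks, `[[`, "data")) / length(warped_masks)
  vol3d(avg, spacing = warped_masks[[1]]$spacing)
}

#' Trace a VOI from a label probability map
#'
#' The bounding box of all voxels with strictly positive probability,
#' expanded by `padding` voxels on every side and clipped to the image
#' bounds. By construction every hippocampus that contributed to the map is
#' contained within the box.
#'
#' @param prob probability [vol3d] (e.g. from [voi_probability_map()]).
#' @param padding expansion in voxels (default 2).
#' @param side optional side label stored in the result.
#' @return A [voi_spec].
#' @export
define_voi <- function(prob, padding = 2, side = NA_character_) {
  stopifnot(is_vol3d(prob))
  idx <- which(prob$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("probability map has no positive voxels")
  d <- dim(prob$data)
  lo <- pmax(apply(idx, 2, min) - padding, 1L)
  hi <- pmin(apply(idx, 2, max) + padding, d)
  voi_spec(lo, hi, side = side, padding = padding)
}

#' Extract the VOI intensity vector
#'
#' Returns the intensities inside the VOI in fixed raster order (x fastest,
#' then y, then z), the order shared by the feature matrices, so that
#' vectors from aligned images are index-aligned voxel by voxel.
#'
#' @param v a [vol3d].
#' @param voi a [voi_spec] within the bounds of `v`.
#' @return Numeric vector of length `prod(voi_dim)`.
#' @export
extract_voi <- function(v, voi) {
  stopifnot(is_vol3d(v), inherits(voi, "voi_spec"))
  if (any(voi$hi > dim(v$data))) stop("VOI exceeds volume bounds")
  as.vector(v$data[voi$lo[1]:voi$hi[1], voi$lo[2]:voi$hi[2],
                   voi$lo[3]:voi$hi[3]])
}

voi_subvolume <- function(v, voi) {
  if (any(voi$hi > dim(v$data))) stop("VOI exceeds volume bounds")
  v$data[voi$lo[1]:voi$hi[1], voi$lo[2]:voi$hi[2], voi$lo[3]:voi$hi[3],
         drop = FALSE]
}

# embed a VOI-shaped array back into a full grid of zeros
embed_voi <- function(sub, voi, fulldim) {
  out <- array(0, fulldim)
  out[voi$lo[1]:voi$hi[1], voi$lo[2]:voi$hi[2], voi$lo[3]:voi$hi[3]] <- sub
  out
}

#' Pearson correlation between two intensity vectors
#'
#' The similarity used for optimal-atlas selection: the product-moment
#' correlation
#' `(N sum(xy) - sum(x) sum(y)) / sqrt((N sum(x^2) - sum(x)^2)(N sum(y^2) - sum(y)^2))`
#' with the sums over all `N` voxels of the peri-hippocampal VOI.
#'
#' @param x,y numeric vectors of equal length `N >= 2`, both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("vectors differ in length")
  if (n < 2) stop("need at least two voxels")
  sx <- sum(x); sy <- sum(y)
  vx <- n * sum(x^2) - sx^2
  vy <- n * sum(y^2) - sy^2
  if (vx <= 0 || vy <= 0)
    stop("correlation undefined: at least one vector is constant")
  r <- (n * sum(x * y) - sx * sy) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Rank candidate atlases by VOI correlation
#'
#' Atlases are sorted by their Pearson correlation with the test VOI in
#' non-increasing order (ties keep input order) and the top `m` are
#' selected; the default `m = 10` follows the usual optimal-atlas count.
#'
#' @param test_voi intensity vector of the scan to segment.
#' @param atlas_vois list of atlas intensity vectors (same length).
#' @param m number of atlases to select (default 10).
#' @param ids optional atlas ids.
#' @return An object of class `atlas_ranking`: a tibble (`atlas`, `r`,
#'   `selected`) sorted by `r`, with attribute `m` = number selected.
#' @export
rank_atlases <- function(test_voi, atlas_vois, m = 10, ids = NULL) {
  if (length(atlas_vois) == 0) stop("empty atlas list")
  if (m < 1) stop("m must be >= 1")
  if (is.null(ids)) ids <- sprintf("atlas%02d", seq_along(atlas_vois))
  r <- vapply(atlas_vois, function(a) pearson_r(a, test_voi), numeric(1))
  ord <- order(-r, seq_along(r))          # ties broken by input order
  k <- min(m, length(atlas_vois))
  out <- tibble::tibble(atlas = ids[ord], r = r[ord],
                        selected = seq_along(ord) <= k)
  class(out) <- c("atlas_ranking", class(out))
  attr(out, "m") <- k
  out
}
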