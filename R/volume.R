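#' 3D volume container
#'
#' `vol3d` is the light in-memory carrier for all image math in the package:
#' a 3D numeric array plus per-axis voxel spacing in millimetres. Voxel
#' indices are 1-based in R code with axis order (x, y, z); all computation
#' is voxel-grid based (the pipeline operates in a common template space, so
#' world-space math is unnecessary). Orientation metadata read from NIfTI is
#' carried along untouched in the `affine` attribute.
#'
#' @param data numeric 3D array; must contain no `NA`/`NaN`.
#' @param spacing numeric length-3, strictly positive voxel size in mm.
#' @param affine optional 4x4 orientation matrix carried as metadata.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  if (anyNA(data)) stop("`data` contains NA/NaN values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel sizes (mm)")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' @rdname vol3d
#' @param x object to test or coerce.
#' @export
is_vol3d <- function(x) inherits(x, "vol3d")

#' Read a volume from a NIfTI file
#'
#' Reads a `.nii`/`.nii.gz` file into a [vol3d]. Only 3D images are
#' accepted; 4D (time-series) images raise an error.
#'
#' @param path path to an existing NIfTI file.
#' @return A [vol3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions in ", path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  arr <- array(as.numeric(img), dim = d)
  if (anyNA(arr)) stop("image contains NA/NaN voxels: ", path)
  vol3d(arr, spacing = sp, affine = structure(RNifti::xform(img), code = NULL))
}

#' Write a volume to a NIfTI file
#'
#' @param v a [vol3d].
#' @param path destination `.nii` or `.nii.gz` path.
#' @param datatype on-disk type, `"float"` (default) or `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float") {
  stopifnot(is_vol3d(v))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Binary mask utilities
#'
#' `as_mask()` binarizes a volume (or array) at a threshold, the convention
#' used when loading warped/interpolated label images: voxels `> threshold`
#' become 1. `volume_of()` returns the labelled volume in cubic millimetres,
#' i.e. the number of 1-voxels times the voxel volume.
#'
#' @param v a [vol3d] or 3D array.
#' @param threshold binarization cut (default 0.5).
#' @param spacing voxel spacing, used when `v` is a bare array.
#' @return `as_mask()`: a [vol3d] whose data is 0/1; `volume_of()`: a scalar
#'   volume in mm^3 (0 for an empty mask).
#' @export
as_mask <- function(v, threshold = 0.5, spacing = c(1, 1, 1)) {
  if (is_vol3d(v)) {
    vol3d((v$data > threshold) + 0, spacing = v$spacing, affine = v$affine)
  } else {
    vol3d((v > threshold) + 0, spacing = spacing)
  }
}

#' @rdname as_mask
#' @param mask a binary [vol3d] (values 0/1).
#' @export
volume_of <- function(mask) {
  stopifnot(is_vol3d(mask))
  check_binary(mask)
  sum(mask$data) * prod(mask$spacing)
}

check_binary <- function(mask) {
  if (!all(mask$data %in% c(0, 1)))
    stop("mask contains values other than 0/1; use as_mask() first")
  invisible(TRUE)
}

#' Dice overlap coefficient
#'
#' Dice index `2|A n B| / (|A| + |B|)` between two binary segmentations of
#' the same grid. Two empty masks are defined to agree perfectly (Dice 1).
#'
#' @param a,b binary [vol3d] masks with identical dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(is_vol3d(a), is_vol3d(b))
  if (!identical(dim(a$data), dim(b$data)))
    stop("mask shapes differ: ", paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  check_binary(a); check_binary(b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data * b$data) / (na + nb)
}
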