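#' Rescale intensities to [0, 1]
#'
#' Linear min-max normalization: the minimum maps to 0 and the maximum to 1.
#' A constant image maps to all zeros rather than NaN, so degenerate inputs
#' cannot poison a pipeline. The operation is idempotent.
#'
#' @param v a [vol3d].
#' @return A [vol3d] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(v) {
  stopifnot(is_vol3d(v))
  r <- range(v$data)
  d <- r[2] - r[1]
  out <- if (d == 0) array(0, dim(v$data)) else (v$data - r[1]) / d
  vol3d(out, spacing = v$spacing, affine = v$affine)
}

#' Polynomial bias-field correction
#'
#' Estimates a smooth multiplicative intensity inhomogeneity (bias field) as
#' a low-order polynomial fitted by least squares to the log-intensities of
#' foreground voxels, divides it out and re-normalizes the result to
#' `[0, 1]`. Foreground is `data > fg_threshold`: with noisy acquisitions
#' the background is not exactly zero, and near-zero voxels would dominate a
#' log-domain fit. The estimated field is normalized to geometric mean 1
#' over the foreground so the overall brightness is preserved. `order = 0`
#' reduces to a global rescale.
#'
#' This is a deliberately simple smooth-field model: any anatomy with
#' low-frequency spatial structure leaks slightly into the estimate, the
#' usual trade-off of polynomial bias correction.
#'
#' @param v a [vol3d], strictly positive on its foreground.
#' @param order total polynomial degree of the field model (default 2).
#' @param fg_threshold intensity above which a voxel counts as foreground
#'   (default 0.05 on `[0, 1]`-normalized scans).
#' @return A bias-corrected, `[0, 1]`-normalized [vol3d] with the estimated
#'   field attached as attribute `"field"`.
#' @export
correct_bias <- function(v, order = 2, fg_threshold = 0.05) {
  stopifnot(is_vol3d(v))
  fg <- v$data > fg_threshold
  if (!any(fg)) stop("all-zero image: no foreground to estimate a bias field")
  d <- dim(v$data)
  idx <- which(fg, arr.ind = TRUE)
  # coordinates scaled to [-1, 1] for a well-conditioned monomial basis
  sc <- function(i, n) if (n > 1) 2 * (i - 1) / (n - 1) - 1 else 0 * i
  X <- poly_basis_3d(sc(idx[, 1], d[1]), sc(idx[, 2], d[2]), sc(idx[, 3], d[3]),
                     order)
  logi <- log(v$data[fg])
  beta <- stats::lm.fit(X, logi)$coefficients
  beta[is.na(beta)] <- 0
  logfield <- drop(X %*% beta)
  logfield <- logfield - mean(logfield)   # geometric mean 1 on foreground
  out <- v$data
  out[fg] <- v$data[fg] / exp(logfield)
  field <- array(1, d)
  field[fg] <- exp(logfield)
  res <- normalize_intensity(vol3d(out, spacing = v$spacing, affine = v$affine))
  attr(res, "field") <- field
  res
}

poly_basis_3d <- function(x, y, z, order) {
  cols <- list(rep(1, length(x)))
  for (total in seq_len(order)) {
    for (i in total:0) for (j in (total - i):0) {
      k <- total - i - j
      cols[[length(cols) + 1L]] <- x^i * y^j * z^k
    }
  }
  do.call(cbind, cols)
}

# ---- affine transforms ------------------------------------------------------

#' Affine transform (pull convention)
#'
#' A 12-parameter linear map in voxel units. The convention throughout the
#' package is the *pull* (resampling) convention: the transform maps
#' fixed-space voxel coordinates `u` to moving-space coordinates via
#' `A (u - center) + center + trans`, and resampling evaluates the moving
#' image at those coordinates.
#'
#' @param A invertible 3x3 matrix.
#' @param trans length-3 translation (voxels).
#' @param center length-3 rotation/scaling centre in fixed-space voxel
#'   coordinates (0-based).
#' @return An object of class `affine3d`.
#' @export
affine3d <- function(A = diag(3), trans = c(0, 0, 0), center = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  if (abs(det(A)) < 1e-8) stop("affine matrix is (near-)singular")
  structure(list(A = A, trans = as.numeric(trans), center = as.numeric(center),
                 converged = TRUE, value = NA_real_),
            class = "affine3d")
}

#' @export
print.affine3d <- function(x, ...) {
  cat("<affine3d> trans =", paste(signif(x$trans, 4), collapse = ", "),
      "| det(A) =", signif(det(x$A), 5),
      if (!isTRUE(x$converged)) "| NOT CONVERGED" else "", "\n")
  invisible(x)
}

#' Invert an affine transform
#'
#' @param tf an [affine3d].
#' @return The inverse [affine3d] (maps moving-space to fixed-space
#'   coordinates under the same pull convention).
#' @export
invert_affine <- function(tf) {
  Ai <- solve(tf$A)
  out <- affine3d(Ai, trans = as.numeric(-Ai %*% tf$trans), center = tf$center)
  out$converged <- tf$converged
  out
}

# build a 3x3 matrix from rotation (radians), log-scales and shears
affine_matrix <- function(rot = c(0, 0, 0), logscale = c(0, 0, 0),
                          shear = c(0, 0, 0)) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, shear[1], shear[2]), c(0, 1, shear[3]), c(0, 0, 1))
  Rz %*% Ry %*% Rx %*% diag(exp(logscale)) %*% Sh
}

params_to_affine <- function(p, center) {
  p <- c(p, rep(0, 12 - length(p)))
  affine3d(affine_matrix(p[4:6], p[7:9], p[10:12]), trans = p[1:3],
           center = center)
}

#' Resample a volume through an affine transform
#'
#' Evaluates `v` at the pulled-back coordinates of an output grid, i.e.
#' produces the warped image on the fixed grid. Intensities use trilinear
#' interpolation; masks should use `method = "nearest"`.
#'
#' @param v moving [vol3d].
#' @param tf an [affine3d] mapping output (fixed) coordinates into `v`.
#' @param outdim output grid dimensions (default: same as `v`).
#' @param method `"linear"` or `"nearest"`.
#' @param spacing spacing of the output grid (default: spacing of `v`).
#' @return The resampled [vol3d].
#' @export
apply_affine <- function(v, tf, outdim = dim(v$data), method = "linear",
                         spacing = v$spacing) {
  stopifnot(is_vol3d(v), inherits(tf, "affine3d"))
  m <- match.arg(method, c("linear", "nearest"))
  out <- resample_affine_cpp(v$data, dim(v$data), as.integer(outdim),
                             tf$A, tf$trans, tf$center,
                             if (m == "linear") 0L else 1L, 0)
  vol3d(out, spacing = spacing)
}

# block-mean downsampling by an integer factor (multiresolution pyramid)
downsample_volume <- function(a, f) {
  if (f == 1) return(a)
  d <- dim(a)
  nd <- pmax(1L, d %/% f)
  a <- a[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  b <- array(a, c(f, nd[1], f, nd[2], f, nd[3]))
  apply(b, c(2, 4, 6), mean)
}

#' Intensity-based affine registration
#'
#' Multi-resolution (coarse-to-fine) minimization of the mean squared
#' intensity difference over a 12-parameter affine map, using a
#' derivative-free simplex search at each level with a staged increase in
#' degrees of freedom (translation, then rigid, then full affine). Both
#' images are expected to be normalized to `[0, 1]`. This is a compact
#' general-purpose optimizer intended for template-space pipelines; external
#' registration tools can be plugged in by constructing an [affine3d]
#' directly.
#'
#' @param moving,fixed [vol3d] images on comparable grids.
#' @param levels multiresolution depth (default 3: factors 4, 2, 1).
#' @param dof maximum degrees of freedom: 6 (rigid), 9 (+scale) or 12
#'   (+shear, default).
#' @param maxit simplex iteration cap per stage.
#' @param init optional [affine3d] from a previous registration used as a
#'   warm start (e.g. across template-building iterations).
#' @param restarts maximum fresh-simplex restarts per stage; a restart
#'   escapes a prematurely shrunken simplex and stops early once it stops
#'   improving.
#' @return An [affine3d] mapping fixed coordinates to moving coordinates
#'   (pull convention), with fields `converged` (FALSE flags hitting the
#'   iteration cap; no exception is thrown) and `value` (final mean squared
#'   difference).
#' @export
register_affine <- function(moving, fixed, levels = 3, dof = 12, maxit = 400,
                            init = NULL, restarts = 2) {
  stopifnot(is_vol3d(moving), is_vol3d(fixed))
  if (diff(range(moving$data)) == 0 || diff(range(fixed$data)) == 0) {
    # a constant image gives a flat (ill-posed) cost: identity by convention
    tf <- affine3d(center = (dim(fixed$data) - 1) / 2)
    tf$value <- mean((moving$data - fixed$data)^2)
    attr(tf, "params") <- rep(0, 12)
    return(tf)
  }
  factors <- 2^((levels - 1):0)
  par <- rep(0, 12)
  warm <- !is.null(init) && !is.null(attr(init, "params"))
  if (warm) {
    par <- attr(init, "params")
    factors <- 1                       # refine at full resolution only
    restarts <- 1
    maxit <- min(maxit, 250)
  }
  conv <- TRUE
  value <- NA_real_
  parscale <- c(rep(1, 3), rep(0.05, 3), rep(0.05, 3), rep(0.05, 3))
  for (li in seq_along(factors)) {
    f <- factors[li]
    mv <- downsample_volume(moving$data, f)
    fx <- downsample_volume(fixed$data, f)
    ctr <- (dim(fx) - 1) / 2
    par[1:3] <- par[1:3] / f        # translations live in level voxels
    stages <- if (li == 1 && !warm) list(1:3, seq_len(min(6, dof)))
              else list(seq_len(min(6, dof)), seq_len(dof))
    stages <- unique(stages)
    for (active in stages) {
      fn <- function(q) {
        p <- par; p[active] <- q
        tf <- params_to_affine(p, ctr)
        msd_affine_cpp(mv, dim(mv), fx, dim(fx), tf$A, tf$trans, tf$center, 1L)
      }
      # Nelder-Mead with simplex restarts: a fresh simplex escapes the
      # shrunken one, which matters on piecewise-smooth cost surfaces
      best <- Inf
      for (r in seq_len(restarts)) {
        o <- stats::optim(par[active], fn, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-8,
                                         parscale = parscale[active]))
        par[active] <- o$par
        value <- o$value
        conv <- o$convergence == 0     # state of the most recent search
        if (best - o$value < 1e-9 + 1e-4 * best) {
          best <- o$value
          break
        }
        best <- o$value
      }
    }
    par[1:3] <- par[1:3] * f
  }
  tf <- params_to_affine(par, (dim(fixed$data) - 1) / 2)
  tf$converged <- conv
  tf$value <- value
  attr(tf, "params") <- par
  tf
}

# ---- non-linear (demons-like) registration ---------------------------------

#' Dense displacement field
#'
#' Container for a voxelwise displacement field on the fixed grid:
#' `warped(x) = moving(x + u(x))` (pull convention, voxel units).
#'
#' @param ux,uy,uz 3D arrays of per-axis displacements (voxels).
#' @return An object of class `disp_field`.
#' @export
disp_field <- function(ux, uy, uz) {
  stopifnot(identical(dim(ux), dim(uy)), identical(dim(ux), dim(uz)))
  structure(list(ux = ux, uy = uy, uz = uz), class = "disp_field")
}

#' Diffusion-regularized non-linear registration
#'
#' A demons-style refinement to be applied after affine pre-alignment:
#' `moving` and `fixed` must already live on the same grid. Each iteration
#' takes a gradient-descent step on the local squared intensity difference
#' (with the classic demons normalization) and smooths the accumulated
#' displacement field with a Gaussian of standard deviation `smoothness`
#' voxels, which keeps the Jacobian bounded (no folding at the default
#' regularization). Zero iterations return the zero field.
#'
#' @param moving,fixed [vol3d] images on the same grid, affinely pre-aligned.
#' @param smoothness Gaussian sigma (voxels) of the field regularizer.
#' @param iterations number of demons iterations.
#' @param step gradient step length.
#' @return A [disp_field] on the fixed grid.
#' @export
register_nonlinear <- function(moving, fixed, smoothness = 1.5,
                               iterations = 20, step = 1) {
  stopifnot(is_vol3d(moving), is_vol3d(fixed))
  if (!identical(dim(moving$data), dim(fixed$data)))
    stop("moving and fixed must share a grid (apply the affine first)")
  d <- dim(fixed$data)
  ux <- uy <- uz <- array(0, d)
  eps <- 1e-6
  for (it in seq_len(iterations)) {
    w <- sample_displaced_cpp(moving$data, d, ux, uy, uz)
    diffim <- w - fixed$data
    g <- central_gradient(w)
    denom <- g$gx^2 + g$gy^2 + g$gz^2 + diffim^2 + eps
    ux <- smooth3_gauss_cpp(ux - step * diffim * g$gx / denom, d, smoothness)
    uy <- smooth3_gauss_cpp(uy - step * diffim * g$gy / denom, d, smoothness)
    uz <- smooth3_gauss_cpp(uz - step * diffim * g$gz / denom, d, smoothness)
  }
  disp_field(ux, uy, uz)
}

central_gradient <- function(a) {
  d <- dim(a)
  shift <- function(arr, by, axis) {
    idx <- lapply(d, seq_len)
    idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
    do.call(`[`, c(list(arr), idx))
  }
  list(gx = (shift(a, 1L, 1) - shift(a, -1L, 1)) / 2,
       gy = (shift(a, 1L, 2) - shift(a, -1L, 2)) / 2,
       gz = (shift(a, 1L, 3) - shift(a, -1L, 3)) / 2)
}

#' Warp a volume through an affine and/or displacement field
#'
#' Composes the affine map with a displacement field defined on the output
#' grid: the sampled moving-space coordinate of output voxel `u` is
#' `Affine(u + disp(u))` (the field refines fixed-space coordinates before
#' the affine pulls them into the moving image). With only one of the two
#' supplied the other is the identity.
#'
#' @param v moving [vol3d].
#' @param tf an [affine3d] or `NULL`.
#' @param field a [disp_field] on the output grid or `NULL`.
#' @param outdim output grid dimensions.
#' @param method `"linear"` or `"nearest"` (masks). With a displacement
#'   field, `"nearest"` is approximated by trilinear sampling followed by
#'   binarization at 0.5.
#' @return The warped [vol3d].
#' @export
warp_volume <- function(v, tf = NULL, field = NULL, outdim = dim(v$data),
                        method = "linear") {
  stopifnot(is_vol3d(v))
  if (is.null(field)) {
    if (is.null(tf)) tf <- affine3d()
    return(apply_affine(v, tf, outdim = outdim, method = method))
  }
  d <- as.integer(outdim)
  ax <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), d)
  ay <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), d)
  az <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), d)
  px <- ax + field$ux; py <- ay + field$uy; pz <- az + field$uz
  if (!is.null(tf)) {
    q <- rbind(as.vector(px) - tf$center[1],
               as.vector(py) - tf$center[2],
               as.vector(pz) - tf$center[3])
    q <- tf$A %*% q + tf$center + tf$trans
    px <- array(q[1, ], d); py <- array(q[2, ], d); pz <- array(q[3, ], d)
  }
  out <- sample_displaced_cpp(v$data, d, px - ax, py - ay, pz - az)
  if (match.arg(method, c("linear", "nearest")) == "nearest")
    out <- (out > 0.5) + 0
  vol3d(out, spacing = v$spacing)
}

# ---- template construction --------------------------------------------------

#' Build a data-driven intensity template
#'
#' Iterative population averaging: the initial reference is the voxelwise
#' mean of all scans after rigid alignment to the first scan; each iteration
#' then registers every scan affinely to the current reference and averages
#' the warped images. All scans must be normalized to `[0, 1]`; the template
#' intensities stay in `[0, 1]` (a mean of bounded images).
#'
#' @param scans list of normalized [vol3d] scans on a common grid.
#' @param iterations number of refinement iterations (default 2).
#' @param ids optional character ids recorded as provenance.
#' @param levels,maxit forwarded to [register_affine()].
#' @return An object of class `template`: fields `volume` ([vol3d]),
#'   `provenance`, `iterations` and `transforms` (the last-iteration
#'   [affine3d] per scan, usable to warp the scans' labels).
#' @export
build_template <- function(scans, iterations = 2, ids = NULL, levels = 3,
                           maxit = 400) {
  if (length(scans) == 0) stop("need at least one scan")
  stopifnot(all(vapply(scans, is_vol3d, TRUE)))
  if (is.null(ids)) ids <- sprintf("scan%02d", seq_along(scans))
  d <- dim(scans[[1]]$data)
  tfs <- vector("list", length(scans))
  if (length(scans) == 1) {
    tfs[[1]] <- affine3d(center = (d - 1) / 2)
    return(structure(list(volume = scans[[1]], provenance = ids,
                          iterations = 0L, transforms = tfs),
                     class = "template"))
  }
  # initial reference: rigid alignment to the first scan, then mean
  warped <- vector("list", length(scans))
  warped[[1]] <- scans[[1]]
  tfs[[1]] <- affine3d(center = (d - 1) / 2)
  for (i in seq_along(scans)[-1]) {
    tfs[[i]] <- register_affine(scans[[i]], scans[[1]], levels = levels,
                                dof = 6, maxit = maxit)
    warped[[i]] <- apply_affine(scans[[i]], tfs[[i]], outdim = d)
  }
  ref <- Reduce(`+`, lapply(warped, `[[`, "data")) / length(scans)
  refv <- vol3d(ref, spacing = scans[[1]]$spacing)
  for (it in seq_len(iterations)) {
    for (i in seq_along(scans)) {
      tfs[[i]] <- register_affine(scans[[i]], refv, levels = levels,
                                  maxit = maxit,
                                  init = if (it > 1) tfs[[i]])
      warped[[i]] <- apply_affine(scans[[i]], tfs[[i]], outdim = d)
    }
    ref <- Reduce(`+`, lapply(warped, `[[`, "data")) / length(scans)
    refv <- vol3d(pmin(pmax(ref, 0), 1), spacing = scans[[1]]$spacing)
  }
  structure(list(volume = refv, provenance = ids,
                 iterations = as.integer(iterations), transforms = tfs),
            class = "template")
}

#' @export
print.template <- function(x, ...) {
  cat(sprintf("<template> %s voxels, %d contributing scans, %d iterations\n",
              paste(dim(x$volume$data), collapse = "x"),
              length(x$provenance), x$iterations))
  invisible(x)
}
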