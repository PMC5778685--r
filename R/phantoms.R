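#' Specification of a synthetic brain phantom
#'
#' Parameters of the T1-like test phantom: a three-tissue brain ellipsoid
#' (cortical shell, inner white matter, central ventricle) containing two
#' bent-ellipsoid hippocampi of controlled volume placed symmetrically about
#' the midline, corrupted by a smooth multiplicative bias field, additive
#' Gaussian noise and a random rigid pose jitter. The default target volume
#' is the mean training hippocampal volume of 2650.2 mm^3; the default grid
#' is 64^3 at 1 mm isotropic, which keeps the full pipeline desk-scale.
#' Pose jitter is rigid by default (rotation + translation) so the
#' ground-truth volume is preserved up to voxelization; anatomical size
#' variation is expressed through the target volumes instead.
#'
#' @param shape grid dimensions (default `c(64, 64, 64)`).
#' @param spacing voxel size in mm (default 1 mm isotropic).
#' @param volume_left,volume_right target hippocampal volumes in mm^3.
#' @param tissue_levels intensities of shell, white matter, ventricle.
#' @param hippo_level hippocampus intensity.
#' @param bias_amplitude peak relative amplitude of the bias field.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param max_translation,max_rotation_deg,max_logscale pose jitter ranges.
#' @param seed RNG seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         volume_left = 2650.2, volume_right = 2650.2,
                         tissue_levels = c(shell = 0.45, white = 0.65,
                                           ventricle = 0.2),
                         hippo_level = 0.9,
                         bias_amplitude = 0.1, noise_sd = 0.02,
                         max_translation = 3, max_rotation_deg = 5,
                         max_logscale = 0, seed = 1) {
  if (volume_left <= 0 || volume_right <= 0) stop("target volumes must be > 0")
  if (noise_sd < 0) stop("noise sd must be >= 0")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 volume_left = volume_left, volume_right = volume_right,
                 tissue_levels = tissue_levels, hippo_level = hippo_level,
                 bias_amplitude = bias_amplitude, noise_sd = noise_sd,
                 max_translation = max_translation,
                 max_rotation_deg = max_rotation_deg,
                 max_logscale = max_logscale, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic brain phantom with ground-truth hippocampus masks
#'
#' Deterministic given the spec's seed. The returned masks are the ground
#' truth *before* intensity corruption (they share the image's pose jitter,
#' since the jitter moves the anatomy itself).
#'
#' @param spec a [phantom_spec()].
#' @return A list `image` ([vol3d]), `mask_left`, `mask_right` (binary
#'   [vol3d]) and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  sc <- d / 64                         # geometry scales with the grid
  ctr <- (d + 1) / 2
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  ell <- function(cx, cy, cz, rx, ry, rz)
    ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 + ((Z - cz) / rz)^2 <= 1
  brain <- ell(ctr[1], ctr[2], ctr[3], 26 * sc[1], 29 * sc[2], 24 * sc[3])
  white <- ell(ctr[1], ctr[2], ctr[3], 19 * sc[1], 22 * sc[2], 17 * sc[3])
  vent <- ell(ctr[1], ctr[2] + 4 * sc[2], ctr[3] + 6 * sc[3],
              5 * sc[1], 9 * sc[2], 5 * sc[3])
  lv <- spec$tissue_levels
  img <- array(0, d)
  img[brain] <- lv[["shell"]]
  img[white] <- lv[["white"]]
  img[vent] <- lv[["ventricle"]]

  # bent-ellipsoid hippocampus: elongated along y, sheared towards the
  # midline as |y| grows (unit-Jacobian shear, so the volume is the
  # ellipsoid's)
  hippo_mask <- function(side_sign, target_mm3) {
    vox <- target_mm3 / prod(spec$spacing)
    r <- (vox / (4 / 3 * pi * 2.2 * 0.9))^(1 / 3)
    a <- r; b <- 2.2 * r; cc <- 0.9 * r
    hx <- ctr[1] + side_sign * 11 * sc[1]
    hy <- ctr[2] - 2 * sc[2]
    hz <- ctr[3] - 4 * sc[3]
    u <- X - hx; v <- Y - hy; w <- Z - hz
    ub <- u + side_sign * 0.35 * a * (v / b)^2   # bend
    (ub / a)^2 + (v / b)^2 + (w / cc)^2 <= 1
  }
  brain_mm3 <- sum(brain) * prod(spec$spacing)
  if (spec$volume_left + spec$volume_right >= brain_mm3)
    stop("hippocampus volume exceeds the brain volume")
  ml <- hippo_mask(-1, spec$volume_left)
  mr <- hippo_mask(+1, spec$volume_right)
  img[ml | mr] <- spec$hippo_level

  # rigid(+scale) pose jitter applied to anatomy and masks alike
  rot <- runif(3, -1, 1) * spec$max_rotation_deg * pi / 180
  trn <- runif(3, -1, 1) * spec$max_translation
  lsc <- runif(3, -1, 1) * spec$max_logscale
  tf <- affine3d(affine_matrix(rot, lsc), trans = trn, center = (d - 1) / 2)
  imgv <- apply_affine(vol3d(img, spec$spacing), tf)
  mlv <- apply_affine(vol3d(ml + 0, spec$spacing), tf, method = "nearest")
  mrv <- apply_affine(vol3d(mr + 0, spec$spacing), tf, method = "nearest")

  # smooth multiplicative bias + additive noise on the image only
  out <- imgv$data
  if (spec$bias_amplitude > 0) {
    g <- runif(3, -1, 1); g <- g / max(abs(g), 1e-9)
    q <- runif(1, -1, 1)
    nx <- (X - ctr[1]) / d[1]; ny <- (Y - ctr[2]) / d[2]
    nz <- (Z - ctr[3]) / d[3]
    p <- g[1] * nx + g[2] * ny + g[3] * nz + q * (nx^2 + ny^2 + nz^2)
    p <- p / max(abs(p))
    out <- out * (1 + spec$bias_amplitude * p)
  }
  if (spec$noise_sd > 0)
    out <- pmax(out + rnorm(length(out), sd = spec$noise_sd), 0)
  list(image = vol3d(out, spec$spacing), mask_left = mlv, mask_right = mrv,
       spec = spec)
}

#' Specification of a synthetic diagnostic cohort
#'
#' Statistical structure of the generated subjects: group sizes and age
#' distributions follow the reference test cohort (145 CTRL aged 73 +- 6,
#' 217 MCI aged 75 +- 9, 94 AD aged 75 +- 9, truncated to 55-95 years);
#' the true volume of a control follows the linear aging model
#' `V0 + k (age - t0)` with `V0 = 3173.0` mm^3 and `k = -29.9` mm^3/yr, MCI
#' and AD subjects get group atrophy offsets subtracted; a subject random
#' effect (sd 150 mm^3) and per-scan measurement noise (sd `84.3/sqrt(2)`
#' mm^3, so that screening-repeat residuals have sd 84.3 mm^3) complete the
#' model. Follow-up scans atrophy at a group-specific annual rate.
#'
#' @param n named group sizes.
#' @param age_mean,age_sd,age_range group age distributions (years).
#' @param V0 intercept of the control aging line (mm^3).
#' @param k aging slope (mm^3 per year, negative = atrophy).
#' @param offsets group atrophy offsets (mm^3, subtracted from the line).
#' @param subject_sd between-subject sd of the true volume (mm^3).
#' @param measurement_sd per-scan measurement noise sd (mm^3).
#' @param asym_right right-minus-left volume asymmetry (mm^3).
#' @param annual_atrophy per-group annual volume loss for follow-ups
#'   (mm^3/year).
#' @param timepoints time points generated by [make_longitudinal()].
#' @param seed RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(CTRL = 145, MCI = 217, AD = 94),
                        age_mean = c(CTRL = 73, MCI = 75, AD = 75),
                        age_sd = c(CTRL = 6, MCI = 9, AD = 9),
                        age_range = c(55, 95),
                        V0 = 3173.0, k = -29.9,
                        offsets = c(CTRL = 0, MCI = 250, AD = 500),
                        subject_sd = 150, measurement_sd = 84.3 / sqrt(2),
                        asym_right = 60,
                        annual_atrophy = c(CTRL = 30, MCI = 60, AD = 100),
                        timepoints = c("screening", "repeat", "m12", "m24"),
                        seed = 1) {
  if (any(n < 1)) stop("group sizes must be >= 1")
  if (any(offsets < 0)) stop("atrophy offsets must be >= 0")
  structure(list(n = n, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, V0 = V0, k = k, offsets = offsets,
                 subject_sd = subject_sd, measurement_sd = measurement_sd,
                 asym_right = asym_right, annual_atrophy = annual_atrophy,
                 timepoints = timepoints, seed = as.integer(seed)),
            class = "cohort_spec")
}

truncated_normal <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}

#' Generate a synthetic diagnostic cohort (screening time point)
#'
#' One row per subject with measured left/right volumes at screening, plus
#' the generator's true (noise-free) volumes in `true_left_mm3` /
#' `true_right_mm3` for ground-truth checks. The reference age `t0` is the
#' minimum age of the generated cohort and is attached as attribute `"t0"`.
#' Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `id`, `age`, `group`, `timepoint`,
#'   `v_left_mm3`, `v_right_mm3`, `true_left_mm3`, `true_right_mm3`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(names(spec$n), times = spec$n)
  n <- length(groups)
  age <- numeric(n)
  for (g in names(spec$n)) {
    i <- groups == g
    age[i] <- truncated_normal(sum(i), spec$age_mean[[g]], spec$age_sd[[g]],
                               spec$age_range[1], spec$age_range[2])
  }
  t0 <- min(age)
  subj <- rnorm(n, 0, spec$subject_sd)
  true_left <- spec$V0 + spec$k * (age - t0) - spec$offsets[groups] + subj
  true_right <- true_left + spec$asym_right
  out <- tibble::tibble(
    id = sprintf("sub%04d", seq_len(n)),
    age = age, group = groups, timepoint = "screening",
    v_left_mm3 = true_left + rnorm(n, 0, spec$measurement_sd),
    v_right_mm3 = true_right + rnorm(n, 0, spec$measurement_sd),
    true_left_mm3 = unname(true_left), true_right_mm3 = unname(true_right))
  attr(out, "t0") <- t0
  out
}

#' Generate a longitudinal cohort across time points
#'
#' Screening and repeat scans share the same true volume (they are acquired
#' within weeks) and differ only by measurement noise; 12- and 24-month
#' follow-ups subtract the group-specific annual atrophy from the true
#' volume. The `age` column holds the baseline age throughout.
#'
#' @inheritParams make_cohort
#' @return A tibble with `length(spec$timepoints)` rows per subject.
#' @export
make_longitudinal <- function(spec = cohort_spec()) {
  base <- make_cohort(spec)
  t0 <- attr(base, "t0")
  years <- c(screening = 0, "repeat" = 0, m12 = 1, m24 = 2)
  unknown <- setdiff(spec$timepoints, names(years))
  if (length(unknown) > 0) stop("unknown time point(s): ",
                                paste(unknown, collapse = ", "))
  out <- purrr::map_dfr(spec$timepoints, function(tp) {
    dt <- years[[tp]]
    atro <- spec$annual_atrophy[base$group] * dt
    tl <- base$true_left_mm3 - atro
    tr <- base$true_right_mm3 - atro
    tibble::tibble(
      id = base$id, age = base$age, group = base$group, timepoint = tp,
      v_left_mm3 = tl + rnorm(nrow(base), 0, spec$measurement_sd),
      v_right_mm3 = tr + rnorm(nrow(base), 0, spec$measurement_sd),
      true_left_mm3 = unname(tl), true_right_mm3 = unname(tr))
  })
  attr(out, "t0") <- t0
  out
}

#' Cohort boxplot by diagnostic group
#'
#' @param records cohort tibble.
#' @param timepoint time point to plot.
#' @return A ggplot.
#' @export
plot_cohort_volumes <- function(records, timepoint = "screening") {
  df <- records[records$timepoint == timepoint, ] |>
    tidyr::pivot_longer(cols = c("v_left_mm3", "v_right_mm3"),
                        names_to = "side", values_to = "volume") |>
    dplyr::mutate(side = ifelse(.data$side == "v_left_mm3", "left", "right"),
                  group = factor(.data$group, c("CTRL", "MCI", "AD")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$volume,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = NULL, y = "hippocampal volume (mm^3)",
                  title = paste("Volumes by diagnostic group:", timepoint))
}
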