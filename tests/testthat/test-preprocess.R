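test_that("normalize_intensity rescales linearly and is idempotent", {
  v <- vol3d(array(c(10, 20, 30, 10, 30, 20, 10, 10), c(2, 2, 2)))
  n <- normalize_intensity(v)
  expect_equal(sort(unique(as.vector(n$data))), c(0, 0.5, 1))
  expect_equal(n$data[1, 1, 1], 0)
  expect_equal(normalize_intensity(n)$data, n$data)
  # already-[0,1] image with attained endpoints is unchanged
  u <- rand_vol(seed = 2)
  u$data[1] <- 0; u$data[2] <- 1
  expect_equal(normalize_intensity(u)$data, u$data)
  # constant image maps to zeros, not NaN
  k <- vol3d(array(0.7, c(3, 3, 3)))
  expect_true(all(normalize_intensity(k)$data == 0))
})

test_that("bias correction removes a known multiplicative ramp", {
  # single-tissue foreground: a solid ball, intensity 0.8
  d <- c(24, 24, 24)
  x <- seq_len(d[1]); ctr <- (d + 1) / 2
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(x, each = d[1]), times = d[3]), d)
  Z <- array(rep(x, each = d[1] * d[2]), d)
  ball <- ((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2) <= 9^2
  clean <- array(0, d); clean[ball] <- 0.8
  cleanv <- normalize_intensity(vol3d(clean))

  # bias-free input passes through nearly unchanged
  out0 <- correct_bias(cleanv, order = 2)
  expect_lt(sqrt(mean((out0$data - cleanv$data)^2)), 0.01)

  # linear ramp field: corrected RMS error shrinks by >= 50%
  ramp <- 1 + 0.3 * (X - ctr[1]) / d[1]
  biased <- normalize_intensity(vol3d(clean * ramp))
  corr <- correct_bias(biased, order = 2)
  rms_before <- sqrt(mean((biased$data - cleanv$data)^2))
  rms_after <- sqrt(mean((corr$data - cleanv$data)^2))
  expect_lt(rms_after, 0.5 * rms_before)

  # order 0 is a global rescale: output proportional to input on foreground
  out_g <- correct_bias(biased, order = 0)
  fg <- biased$data > 0
  ratio <- out_g$data[fg] / biased$data[fg]
  expect_lt(diff(range(ratio)), 1e-10)

  expect_error(correct_bias(vol3d(array(0, c(4, 4, 4)))), "all-zero")
})

test_that("self-registration is the identity and known shifts are recovered", {
  ph <- clean_phantom(seed = 5)
  v <- normalize_intensity(ph$image)
  tf <- register_affine(v, v)
  expect_lt(max(abs(tf$trans)), 0.1)
  expect_lt(max(abs(tf$A - diag(3))), 0.01)

  # moving built by pulling with t = +3 along x; registration recovers -3
  ctr <- (dim(v$data) - 1) / 2
  mv <- apply_affine(v, affine3d(diag(3), trans = c(3, 0, 0), center = ctr))
  tf2 <- register_affine(mv, v)
  expect_lt(max(abs(tf2$trans - c(-3, 0, 0))), 0.5)

  # 5 degree rotation about z recovered within 1 degree
  ang <- 5 * pi / 180
  A <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  mv2 <- apply_affine(v, affine3d(A, center = ctr))
  tf3 <- register_affine(mv2, v)
  rec <- atan2(tf3$A[2, 1], tf3$A[1, 1]) * 180 / pi
  expect_lt(abs(rec - (-5)), 1)
})

test_that("random small affine perturbations are recovered (>=90% MSD drop)", {
  ph <- clean_phantom(seed = 6)
  v <- normalize_intensity(ph$image)
  ctr <- (dim(v$data) - 1) / 2
  set.seed(11)
  for (rep in 1:3) {
    rot <- runif(3, -1, 1) * 10 * pi / 180
    trn <- runif(3, -1, 1) * 5
    tf_true <- affine3d(hippmas:::affine_matrix(rot), trans = trn,
                        center = ctr)
    mv <- apply_affine(v, tf_true)
    msd0 <- mean((mv$data - v$data)^2)
    tf <- register_affine(mv, v)
    w <- apply_affine(mv, tf)
    msd1 <- mean((w$data - v$data)^2)
    # the attainable floor is the inverse of the generating transform
    # (double interpolation leaves an irreducible residual)
    wf <- apply_affine(mv, invert_affine(tf_true))
    msd_floor <- mean((wf$data - v$data)^2)
    expect_lt(msd1, max(0.1 * msd0, 1.1 * msd_floor))
  }
})

test_that("demons refinement behaves at its fixed points and improves overlap", {
  ph <- clean_phantom(seed = 7)
  v <- normalize_intensity(ph$image)
  # identical images -> near-zero field
  f0 <- register_nonlinear(v, v, iterations = 10)
  expect_lt(max(abs(c(f0$ux, f0$uy, f0$uz))), 0.1)
  # zero iterations -> exactly zero field
  fz <- register_nonlinear(v, v, iterations = 0)
  expect_true(all(c(fz$ux, fz$uy, fz$uz) == 0))

  # hippocampi ~10% larger: non-linear refinement improves mask Dice over
  # the (identity) affine alignment
  big <- make_phantom(phantom_spec(volume_left = 2650.2 * 1.35,
                                   volume_right = 2650.2 * 1.35,
                                   noise_sd = 0, bias_amplitude = 0,
                                   max_translation = 0, max_rotation_deg = 0,
                                   seed = 7))
  bv <- normalize_intensity(big$image)
  fld <- register_nonlinear(bv, v, iterations = 30, smoothness = 1.5)
  warped_mask <- warp_volume(big$mask_left, field = fld, method = "nearest")
  expect_gt(dice(warped_mask, ph$mask_left),
            dice(big$mask_left, ph$mask_left))

  # no folding: Jacobian of (id + u) stays positive
  g <- hippmas:::central_gradient
  jx <- g(fld$ux); jy <- g(fld$uy); jz <- g(fld$uz)
  detj <- (1 + jx$gx) * ((1 + jy$gy) * (1 + jz$gz) - jy$gz * jz$gy) -
    jx$gy * (jy$gx * (1 + jz$gz) - jy$gz * jz$gx) +
    jx$gz * (jy$gx * jz$gy - (1 + jy$gy) * jz$gx)
  expect_gt(min(detj), 0)
})

test_that("template building averages aligned scans", {
  ph <- clean_phantom(seed = 8)
  v <- normalize_intensity(ph$image)
  t1 <- build_template(list(v), iterations = 2)
  expect_equal(t1$volume$data, v$data)

  t2 <- build_template(list(v, v), iterations = 1)
  expect_lt(max(abs(t2$volume$data - v$data)), 0.02)
  expect_true(all(t2$volume$data >= 0 & t2$volume$data <= 1))

  c1 <- vol3d(array(0.2, c(8, 8, 8)))
  c2 <- vol3d(array(0.4, c(8, 8, 8)))
  t3 <- build_template(list(c1, c2), iterations = 1)
  expect_equal(unique(as.vector(t3$volume$data)), 0.3)

  expect_error(build_template(list()), "at least one")
})
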