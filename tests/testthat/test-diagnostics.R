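test_that("precision report summarizes screening-repeat residuals", {
  same <- data.frame(v_screening = c(2600, 2700, 2800),
                     v_repeat = c(2600, 2700, 2800))
  p0 <- precision_report(same, 2650)
  expect_equal(p0$mean_residual, 0)
  expect_equal(p0$sd_residual, 0)
  p1 <- precision_report(data.frame(v_screening = c(2, 2),
                                    v_repeat = c(3, 1)), 100)
  expect_equal(p1$mean_residual, 0)
  expect_equal(p1$sd_residual, sqrt(2))
  expect_error(precision_report(same[1, ], 2650), "at least 2")
  # invariance to a common shift of both scans of every pair
  set.seed(1)
  a <- rnorm(50, 2650, 100); b <- rnorm(50, 2650, 100)
  pa <- precision_report(data.frame(v_screening = a, v_repeat = b), 2650)
  pb <- precision_report(data.frame(v_screening = a + 300,
                                    v_repeat = b + 300), 2650)
  expect_equal(pa$sd_residual, pb$sd_residual)
})

test_that("time-point correlation matrices behave structurally", {
  set.seed(2)
  n <- 200
  base <- tibble::tibble(id = sprintf("s%03d", 1:n), age = runif(n, 60, 90),
                         group = "CTRL")
  dup <- dplyr::bind_rows(
    dplyr::mutate(base, timepoint = "screening",
                  v_left_mm3 = rnorm(n, 2600, 200)),
    dplyr::mutate(base, timepoint = "repeat", v_left_mm3 = NA))
  dup$v_left_mm3[dup$timepoint == "repeat"] <-
    dup$v_left_mm3[dup$timepoint == "screening"]
  dup$v_right_mm3 <- dup$v_left_mm3
  tc <- timepoint_correlations(dup)
  expect_true(all(abs(tc$left - 1) < 1e-12))
  # independent volumes: small off-diagonal r, symmetric unit-diagonal
  ind <- dplyr::bind_rows(
    dplyr::mutate(base, timepoint = "screening",
                  v_left_mm3 = rnorm(n), v_right_mm3 = rnorm(n)),
    dplyr::mutate(base, timepoint = "repeat",
                  v_left_mm3 = rnorm(n), v_right_mm3 = rnorm(n)))
  ti <- timepoint_correlations(ind)
  expect_lt(abs(ti$left["screening", "repeat"]), 0.2)
  expect_equal(ti$left, t(ti$left))
  expect_equal(unname(diag(ti$right)), c(1, 1))
  expect_error(timepoint_correlations(ind, timepoints = c("screening", "m12")),
               "absent")
})

test_that("aging model: exact line, OLS oracle, CI and R^2", {
  ages <- c(60, 65, 70, 75, 80, 85)
  ctrl <- tibble::tibble(age = ages, group = "CTRL",
                         v_left_mm3 = 3000 - 30 * (ages - 60))
  m <- fit_aging_model(ctrl, "left")
  expect_equal(m$V0, 3000)
  expect_equal(m$k, -30)
  expect_equal(m$r2, 1)
  expect_equal(m$t0, 60)

  # closed-form normal-equations oracle on random data
  set.seed(3)
  age <- runif(10, 60, 90)
  v <- rnorm(10, 2800, 200)
  df <- tibble::tibble(age = age, v_left_mm3 = v)
  mm <- fit_aging_model(df, "left")
  x <- age - min(age)
  beta <- solve(cbind(1, x) |> crossprod(),
                crossprod(cbind(1, x), v))
  expect_equal(mm$V0, beta[1], tolerance = 1e-10)
  expect_equal(mm$k, beta[2], tolerance = 1e-10)
  expect_error(fit_aging_model(df[1:2, ], "left"), "at least 3")
  expect_error(fit_aging_model(tibble::tibble(age = rep(70, 5),
                                              v_left_mm3 = rnorm(5)), "left"),
               "degenerate")
})

test_that("detrending matches the printed arithmetic and its identity", {
  ages <- seq(60, 90, length.out = 20)
  ctrl <- tibble::tibble(age = ages,
                         v_left_mm3 = 3173.0 - 29.9 * (ages - 60))
  m <- fit_aging_model(ctrl, "left")
  # V exactly on the line -> 0 at any age
  expect_equal(detrend(3173.0 - 29.9 * 15, 75, m), 0, tolerance = 1e-9)
  # paper-coefficient worked example: age - t0 = 10, V = 2800 -> 74.0
  expect_equal(detrend(2800, 70, m), 74.0, tolerance = 1e-9)
  # intercept case: age = t0, V = 3000 -> 173.0
  expect_equal(detrend(3000, 60, m), 173.0, tolerance = 1e-9)
  # exactly linear in V with slope -1
  expect_equal(detrend(2000, 70, m) - detrend(2001, 70, m), 1,
               tolerance = 1e-9)
})

test_that("roc_auc matches hand values and brute-force concordance", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_equal(roc_auc(c(0, 2, 1, 3), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  r <- roc_auc(c(0, 2, 1, 3), c(0, 0, 1, 1))
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))

  brute <- function(pos, neg) {
    s <- 0
    for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
    s / (length(pos) * length(neg))
  }
  set.seed(4)
  for (i in 1:20) {
    np <- sample(3:40, 1); nn <- sample(3:40, 1)
    sc <- round(rnorm(np + nn), 1)        # rounding forces ties
    y <- c(rep(1, np), rep(0, nn))
    expect_equal(roc_auc(sc, y)$auc, brute(sc[y == 1], sc[y == 0]),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with pROC on random data", {
  set.seed(5)
  sc <- rnorm(120); y <- rbinom(120, 1, 0.4)
  expect_equal(roc_auc(sc, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("Hanley-McNeil SE matches the closed form", {
  expect_equal(hanley_mcneil_se(1, 10, 10), 0)
  expect_equal(hanley_mcneil_se(0.5, 1, 1), 0.5)
  expect_equal(hanley_mcneil_se(0.8, 10, 10),
               sqrt((0.8 * 0.2 + 9 * (2 / 3 - 0.64) +
                       9 * (1.28 / 1.8 - 0.64)) / 100))
  expect_equal(round(hanley_mcneil_se(0.8, 10, 10), 3), 0.102)
  expect_error(hanley_mcneil_se(0.8, 0, 10), ">= 1")
})

test_that("bootstrap SE is seeded and consistent with Hanley-McNeil", {
  set.seed(6)
  sc <- c(rnorm(100, 1), rnorm(100, 0))
  y <- rep(c(1, 0), each = 100)
  b1 <- bootstrap_auc(sc, y, n_boot = 200, seed = 9)
  b2 <- bootstrap_auc(sc, y, n_boot = 200, seed = 9)
  expect_identical(b1, b2)
  hm <- hanley_mcneil_se(roc_auc(sc, y)$auc, 100, 100)
  expect_lt(abs(b1 - hm) / hm, 0.3)
  expect_warning(b0 <- bootstrap_auc(sc, y, n_boot = 1, seed = 1),
                 "fewer than 2")
  expect_equal(b0, 0)
})

test_that("Kruskal-Wallis matches rank arithmetic", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  k0 <- kruskal_wallis(same)
  expect_lt(k0$H, 1e-9 + 0.5)   # ties push H to ~0 after correction
  expect_gt(k0$p, 0.5)
  k1 <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(k1$H, 32 / 7, tolerance = 1e-12)
  # textbook-formula oracle (no ties)
  set.seed(7)
  g <- list(rnorm(8), rnorm(9, 1), rnorm(7, 2))
  all_v <- unlist(g); rk <- rank(all_v); N <- length(all_v)
  idx <- rep(seq_along(g), lengths(g))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, idx, function(r) length(r) * mean(r)^2)) - 3 * (N + 1)
  k2 <- kruskal_wallis(g)
  expect_equal(k2$H, H, tolerance = 1e-6)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("Naive Bayes 3-class: separable and chance-level cohorts", {
  set.seed(8)
  n <- 100
  sep <- tibble::tibble(
    group = rep(c("CTRL", "MCI", "AD"), each = n),
    v_left_mm3 = c(rnorm(n, 3000, 30), rnorm(n, 2500, 30),
                   rnorm(n, 2000, 30)),
    v_right_mm3 = c(rnorm(n, 3000, 30), rnorm(n, 2500, 30),
                    rnorm(n, 2000, 30)))
  r <- naive_bayes_3class(sep, "both", folds = 5, rounds = 3, seed = 1)
  expect_gte(r$accuracy, 0.95)
  ident <- tibble::tibble(
    group = rep(c("CTRL", "MCI", "AD"), each = n),
    v_left_mm3 = rnorm(3 * n, 2600, 150),
    v_right_mm3 = rnorm(3 * n, 2600, 150))
  rc <- naive_bayes_3class(ident, "both", folds = 5, rounds = 5, seed = 1)
  expect_lt(abs(rc$accuracy - 1 / 3), 0.06)
  expect_error(naive_bayes_3class(sep[sep$group != "AD", ], "both"),
               "three groups")
})
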