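#' Segmentation precision from screening/repeat pairs
#'
#' Screening and repeat scans of the same subject are acquired within weeks,
#' so any difference between their segmented volumes reflects the
#' algorithm's intrinsic uncertainty. The report summarizes the residuals
#' `V_screening - V_repeat`: their mean, sample standard deviation (the
#' precision, in mm^3), the precision as a percentage of a reference mean
#' hippocampal volume, and a one-sample t-test of zero mean (no systematic
#' bias).
#'
#' @param pairs a data frame with columns `v_screening` and `v_repeat`
#'   (mm^3), or a 2-column matrix; at least 2 pairs.
#' @param reference_mean reference mean hippocampal volume in mm^3 used for
#'   the percent precision.
#' @return An object of class `precision_report` with fields `n`,
#'   `mean_residual`, `sd_residual`, `percent`, `p_value`.
#' @export
precision_report <- function(pairs, reference_mean) {
  if (is.matrix(pairs)) pairs <- data.frame(v_screening = pairs[, 1],
                                            v_repeat = pairs[, 2])
  stopifnot(all(c("v_screening", "v_repeat") %in% names(pairs)))
  if (nrow(pairs) < 2) stop("need at least 2 screening/repeat pairs")
  res <- pairs$v_screening - pairs$v_repeat
  sdr <- stats::sd(res)
  p <- if (sdr > 0) stats::t.test(res, mu = 0)$p.value else 1
  structure(list(n = length(res), mean_residual = mean(res),
                 sd_residual = sdr,
                 percent = 100 * sdr / reference_mean,
                 p_value = p, reference_mean = reference_mean),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf(paste0("<precision_report> n=%d pairs: residuals %.1f +- %.1f",
                     " mm^3 (%.1f%% of %.0f mm^3), H0 mean=0 p=%.3f\n"),
              x$n, x$mean_residual, x$sd_residual, x$percent,
              x$reference_mean, x$p_value))
  invisible(x)
}

#' @export
tidy.precision_report <- function(x, ...) {
  tibble::tibble(n = x$n, mean_residual = x$mean_residual,
                 sd_residual = x$sd_residual, percent = x$percent,
                 p_value = x$p_value)
}

#' Pairwise volume correlations across time points
#'
#' Pearson correlation of segmented volumes between every pair of time
#' points, per hemisphere, over the subjects with all requested time points
#' available. High off-diagonal correlations indicate a longitudinally
#' stable segmentation.
#'
#' @param records cohort tibble with columns `id`, `timepoint`,
#'   `v_left_mm3`, `v_right_mm3`.
#' @param timepoints time points to correlate (default: all present).
#' @return An object of class `timepoint_cor`: a named list of per-side
#'   correlation matrices, with a [tidy()] method returning the long form.
#' @export
timepoint_correlations <- function(records, timepoints = NULL) {
  stopifnot(all(c("id", "timepoint", "v_left_mm3", "v_right_mm3") %in%
                  names(records)))
  if (is.null(timepoints)) timepoints <- unique(records$timepoint)
  missing_tp <- setdiff(timepoints, unique(records$timepoint))
  if (length(missing_tp) > 0)
    stop("time point(s) absent from records: ",
         paste(missing_tp, collapse = ", "))
  one_side <- function(col) {
    wide <- records |>
      dplyr::filter(.data$timepoint %in% timepoints) |>
      dplyr::select("id", "timepoint", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "timepoint",
                         values_from = dplyr::all_of(col))
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 3) stop("need >= 3 subjects with all time points")
    stats::cor(as.matrix(wide[, timepoints, drop = FALSE]))
  }
  structure(list(left = one_side("v_left_mm3"),
                 right = one_side("v_right_mm3")),
            class = "timepoint_cor")
}

#' @export
tidy.timepoint_cor <- function(x, ...) {
  purrr::map_dfr(c("left", "right"), function(sd) {
    m <- x[[sd]]
    tibble::tibble(side = sd,
                   from = rep(rownames(m), times = ncol(m)),
                   to = rep(colnames(m), each = nrow(m)),
                   r = as.vector(m))
  })
}

#' @export
print.timepoint_cor <- function(x, ...) {
  for (sd in names(x)) {
    cat(sd, "hippocampus:\n")
    print(round(x[[sd]], 3))
  }
  invisible(x)
}

#' Linear aging model of hippocampal volume
#'
#' Ordinary least squares of volume on age in the control cohort,
#' `V_hat = V0 + k (t - t0)`, with the reference age `t0` fixed at the
#' minimum age of the whole cohort. The slope `k` (mm^3 per year) is the
#' normal-aging atrophy rate; the fit provides `V0`, the 95% confidence
#' interval of `k` and the coefficient of determination.
#'
#' @param ctrl cohort tibble of control subjects with columns `age` and the
#'   side's volume column (`v_left_mm3` / `v_right_mm3`); rows of other
#'   diagnostic groups are dropped if a `group` column is present.
#' @param side `"left"` or `"right"`.
#' @param t0 reference age in years; default `min(ctrl$age)` (pass the
#'   whole-cohort minimum when fitting on a subset).
#' @return An object of class `aging_model` with fields `V0`, `k`, `t0`,
#'   `ci_k`, `se_k`, `se_V0`, `r2`, `n`, `side` and the underlying `lm` fit.
#' @export
fit_aging_model <- function(ctrl, side = c("left", "right"), t0 = NULL) {
  side <- match.arg(side)
  if ("group" %in% names(ctrl)) ctrl <- ctrl[ctrl$group == "CTRL", ]
  col <- paste0("v_", side, "_mm3")
  stopifnot(all(c("age", col) %in% names(ctrl)))
  if (nrow(ctrl) < 3) stop("need at least 3 control records")
  if (length(unique(ctrl$age)) < 2) stop("degenerate fit: all ages identical")
  if (is.null(t0)) t0 <- min(ctrl$age)
  df <- data.frame(v = ctrl[[col]], dt = ctrl$age - t0)
  fit <- stats::lm(v ~ dt, data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit, "dt", level = 0.95)
  structure(list(V0 = unname(coef(fit)[1]), k = unname(coef(fit)[2]),
                 t0 = t0, ci_k = as.numeric(ci),
                 se_k = sm$coefficients["dt", "Std. Error"],
                 se_V0 = sm$coefficients["(Intercept)", "Std. Error"],
                 r2 = sm$r.squared, n = nrow(df), side = side, fit = fit),
            class = "aging_model")
}

#' @export
print.aging_model <- function(x, ...) {
  cat(sprintf(paste0("<aging_model %s> V_hat = %.1f %+.1f (t - %.0f) mm^3,",
                     " 95%% CI(k) [%.1f, %.1f], R^2 = %.3f, n = %d\n"),
              x$side, x$V0, x$k, x$t0, x$ci_k[1], x$ci_k[2], x$r2, x$n))
  invisible(x)
}

#' @export
tidy.aging_model <- function(x, ...) {
  tibble::tibble(term = c("V0", "k"),
                 estimate = c(x$V0, x$k),
                 std.error = c(x$se_V0, x$se_k),
                 conf.low = c(x$V0 - 1.96 * x$se_V0, x$ci_k[1]),
                 conf.high = c(x$V0 + 1.96 * x$se_V0, x$ci_k[2]))
}

#' @export
glance.aging_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, t0 = x$t0, nobs = x$n, side = x$side)
}

#' @export
autoplot.aging_model <- function(object, ...) {
  df <- object$fit$model
  df$age <- df$dt + object$t0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$v)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "firebrick") +
    ggplot2::labs(x = "age (years)", y = "hippocampal volume (mm^3)",
                  title = sprintf("Control aging model (%s): k = %.1f mm^3/yr",
                                  object$side, object$k))
}

#' Remove the normal-aging trend from a volume
#'
#' The effective (age-detrended) volume `V_eff = V_hat(age) - V`, the
#' difference between the volume expected for the subject's age under the
#' control aging model and the measured volume. Larger `V_eff` therefore
#' means a larger atrophy *deficit*, so `V_eff` is used directly as the
#' disease-positive score in ROC analysis. A volume exactly on the model
#' line gives 0 for any age.
#'
#' @param V measured volume(s), mm^3.
#' @param age age(s) in years.
#' @param model an [aging_model].
#' @return `V_eff` in mm^3 (vectorized).
#' @export
detrend <- function(V, age, model) {
  stopifnot(inherits(model, "aging_model"))
  (model$V0 + model$k * (age - model$t0)) - V
}

#' @rdname detrend
#' @param records cohort tibble with `age`, `v_left_mm3`, `v_right_mm3`.
#' @param model_left,model_right per-side [aging_model]s.
#' @return `detrend_cohort()`: `records` with `v_eff_left_mm3` and
#'   `v_eff_right_mm3` columns added.
#' @export
detrend_cohort <- function(records, model_left, model_right) {
  records |>
    dplyr::mutate(
      v_eff_left_mm3 = detrend(.data$v_left_mm3, .data$age, model_left),
      v_eff_right_mm3 = detrend(.data$v_right_mm3, .data$age, model_right))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique score values: at each threshold a subject
#' is called positive when its score strictly exceeds it. The reported AUC
#' is the normalized Mann-Whitney statistic (ties get half credit), which
#' equals the trapezoidal area under the swept curve. The curve starts at
#' (0,0) and ends at (1,1) and both rates are monotone along the sweep.
#' Scores must be oriented so that positives score higher (use `V_eff`, or
#' `-V` for raw volumes).
#'
#' @param scores numeric per-subject scores.
#' @param labels logical/0-1/factor; `positive` names the positive class
#'   when `labels` is a factor or character.
#' @param positive positive class label.
#' @param se also compute the Hanley-McNeil standard error (default TRUE).
#' @return An object of class `roc_result`: `thresholds`, `tpr`, `fpr`,
#'   `auc`, `se_hanley_mcneil`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL, se = TRUE) {
  y <- to_binary_labels(labels, positive)
  if (length(unique(y)) < 2) stop("both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  np <- length(pos); nn <- length(neg)
  rk <- rank(c(pos, neg))
  auc <- (sum(rk[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1); thr <- c(thr, -Inf)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 se_hanley_mcneil = if (se && auc > 0)
                   hanley_mcneil_se(auc, np, nn) else NA_real_,
                 se_bootstrap = NA_real_, n_pos = np, n_neg = nn),
            class = "roc_result")
}

to_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  labels <- as.character(labels)
  if (is.null(positive)) stop("`positive` must name the positive class")
  as.integer(labels == positive)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f +- %.3f (HM)%s, n+ = %d, n- = %d\n",
              x$auc, x$se_hanley_mcneil,
              if (!is.na(x$se_bootstrap))
                sprintf(" / %.3f (bootstrap)", x$se_bootstrap) else "",
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, tpr = x$tpr, fpr = x$fpr)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, se_hanley_mcneil = x$se_hanley_mcneil,
                 se_bootstrap = x$se_bootstrap, n_pos = x$n_pos,
                 n_neg = x$n_neg)
}

#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.2f +- %.2f)", object$auc,
                                  object$se_hanley_mcneil))
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form standard error
#' `SE = sqrt((A(1-A) + (n+ - 1)(Q1 - A^2) + (n- - 1)(Q2 - A^2)) / (n+ n-))`
#' with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param auc the AUC in `(0, 1]`.
#' @param n_pos,n_neg class sizes (>= 1).
#' @return The standard error.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1) stop("class sizes must be >= 1")
  stopifnot(auc > 0, auc <= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Bootstrap standard error of an AUC
#'
#' Resamples subjects with replacement within each class (stratified), 500
#' times by default, and reports the standard deviation of the bootstrap
#' AUCs. Deterministic given the seed.
#'
#' @inheritParams roc_auc
#' @param n_boot bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @return The bootstrap SE (0, with a warning, when `n_boot = 1`).
#' @export
bootstrap_auc <- function(scores, labels, n_boot = 500, seed = 1,
                          positive = NULL) {
  y <- to_binary_labels(labels, positive)
  if (length(unique(y)) < 2) stop("both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  set.seed(seed)
  aucs <- vapply(seq_len(n_boot), function(b) {
    p <- sample(pos, replace = TRUE)
    n <- sample(neg, replace = TRUE)
    rk <- rank(c(p, n))
    (sum(rk[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(n))
  }, numeric(1))
  if (n_boot < 2) {
    warning("fewer than 2 bootstrap replicates: SE reported as 0")
    return(0)
  }
  stats::sd(aucs)
}

#' Kruskal-Wallis group comparison
#'
#' Non-parametric rank test that the volume distributions of the diagnostic
#' groups share a location; the tie-corrected H statistic is referred to a
#' chi-square with k-1 degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 non-empty numeric vectors (volumes per group).
#' @return List with elements `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  if (sum(lengths(groups)) < 5) stop("too few observations")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Three-class Naive Bayes cross-validation
#'
#' Gaussian Naive Bayes classification of CTRL / MCI / AD from hippocampal
#' volumes, evaluated by repeated stratified 10-fold cross-validation.
#' Accuracy is the fraction of correctly classified subjects over the three
#' classes; sensitivity and specificity treat AD as the positive class and
#' MCI + CTRL as negatives. Means and standard deviations are taken across
#' rounds.
#'
#' @param records cohort tibble with `group` and volume columns.
#' @param feature_set `"both"` (left + right volumes as two features),
#'   `"left"` or `"right"`.
#' @param folds cross-validation folds (default 10).
#' @param rounds cross-validation rounds (default 100).
#' @param seed RNG seed.
#' @param columns optional explicit feature column names, overriding
#'   `feature_set` (e.g. detrended volumes).
#' @return A one-row tibble: accuracy / sensitivity / specificity with their
#'   across-round standard deviations, plus `feature_set`, `folds`, `rounds`.
#' @export
naive_bayes_3class <- function(records, feature_set = c("both", "left",
                                                        "right"),
                               folds = 10, rounds = 100, seed = 1,
                               columns = NULL) {
  feature_set <- match.arg(feature_set)
  stopifnot("group" %in% names(records))
  if (!all(c("CTRL", "MCI", "AD") %in% records$group))
    stop("all three groups (CTRL, MCI, AD) must be present")
  if (is.null(columns))
    columns <- switch(feature_set,
                      both = c("v_left_mm3", "v_right_mm3"),
                      left = "v_left_mm3", right = "v_right_mm3")
  X <- as.data.frame(records[, columns, drop = FALSE])
  g <- factor(records$group, levels = c("CTRL", "MCI", "AD"))
  n <- nrow(X)
  set.seed(seed)
  acc <- sens <- spec <- numeric(rounds)
  for (r in seq_len(rounds)) {
    fold_of <- integer(n)
    for (lev in levels(g)) {
      i <- which(g == lev)
      fold_of[sample(i)] <- rep_len(seq_len(folds), length(i))
    }
    pred <- factor(rep(NA_character_, n), levels = levels(g))
    for (f in seq_len(folds)) {
      te <- fold_of == f
      fit <- e1071::naiveBayes(X[!te, , drop = FALSE], g[!te])
      pred[te] <- predict(fit, X[te, , drop = FALSE])
    }
    acc[r] <- mean(pred == g)
    is_ad <- g == "AD"
    sens[r] <- mean(pred[is_ad] == "AD")
    spec[r] <- mean(pred[!is_ad] != "AD")
  }
  tibble::tibble(feature_set = feature_set,
                 accuracy = mean(acc), accuracy_sd = stats::sd(acc),
                 sensitivity = mean(sens), sensitivity_sd = stats::sd(sens),
                 specificity = mean(spec), specificity_sd = stats::sd(spec),
                 folds = folds, rounds = rounds)
}

#' Full volumetric diagnostics report of a longitudinal cohort
#'
#' Convenience wrapper running the whole clinical-evaluation layer on a
#' cohort table: screening/repeat precision, time-point correlations,
#' per-side control aging models, age detrending, per-time-point ROC/AUC
#' tables for CTRL-AD and CTRL-MCI (detrended volumes, averaged over sides,
#' with Hanley-McNeil and bootstrap SEs), Kruskal-Wallis tests and the
#' three-class Naive Bayes table.
#'
#' @param records longitudinal cohort tibble (columns `id`, `age`, `group`,
#'   `timepoint`, `v_left_mm3`, `v_right_mm3`).
#' @param reference_mean reference mean volume for the percent precision.
#' @param n_boot bootstrap replicates for the AUC SE.
#' @param nb_rounds,nb_folds Naive Bayes cross-validation settings.
#' @param seed RNG seed.
#' @return A list of class `cohort_report`.
#' @export
cohort_report <- function(records, reference_mean = 2650.2, n_boot = 500,
                          nb_rounds = 100, nb_folds = 10, seed = 1) {
  tps <- unique(records$timepoint)
  scr <- records[records$timepoint == "screening", ]
  # precision from screening/repeat pairs (mean of both sides per scan)
  prec <- NULL
  if (all(c("screening", "repeat") %in% tps)) {
    # each hippocampus is a measurement: stack left and right pairs
    long <- records |>
      dplyr::filter(.data$timepoint %in% c("screening", "repeat")) |>
      tidyr::pivot_longer(cols = c("v_left_mm3", "v_right_mm3"),
                          names_to = "side", values_to = "v") |>
      tidyr::pivot_wider(id_cols = c("id", "side"),
                         names_from = "timepoint", values_from = "v")
    prec <- precision_report(
      data.frame(v_screening = long$screening, v_repeat = long$`repeat`),
      reference_mean)
  }
  cors <- if (length(tps) > 1) timepoint_correlations(records) else NULL
  t0 <- min(records$age)
  m_left <- fit_aging_model(scr, "left", t0 = t0)
  m_right <- fit_aging_model(scr, "right", t0 = t0)
  auc_tbl <- purrr::map_dfr(tps, function(tp) {
    rec <- detrend_cohort(records[records$timepoint == tp, ], m_left, m_right)
    purrr::map_dfr(c("AD", "MCI"), function(gpos) {
      sub <- rec[rec$group %in% c("CTRL", gpos), ]
      score <- (sub$v_eff_left_mm3 + sub$v_eff_right_mm3) / 2
      roc <- roc_auc(score, sub$group, positive = gpos)
      tibble::tibble(timepoint = tp, task = paste0("CTRL-", gpos),
                     auc = roc$auc, se_hm = roc$se_hanley_mcneil,
                     se_boot = bootstrap_auc(score, sub$group, n_boot = n_boot,
                                             seed = seed, positive = gpos))
    })
  })
  kw <- purrr::map(c(left = "v_left_mm3", right = "v_right_mm3"),
                   function(col) kruskal_wallis(split(scr[[col]], scr$group)))
  nb <- purrr::map_dfr(c("both", "left", "right"), function(fs)
    naive_bayes_3class(scr, fs, folds = nb_folds, rounds = nb_rounds,
                       seed = seed))
  structure(list(precision = prec, correlations = cors,
                 aging_model = list(left = m_left, right = m_right),
                 auc = auc_tbl, kruskal_wallis = kw, naive_bayes = nb),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  if (!is.null(x$precision)) print(x$precision)
  print(x$aging_model$left)
  print(x$aging_model$right)
  cat("AUC (detrended volumes, side-averaged):\n")
  print(as.data.frame(x$auc), digits = 3)
  cat(sprintf("Kruskal-Wallis (screening): left H=%.1f p=%.2g | right H=%.1f p=%.2g\n",
              x$kruskal_wallis$left$H, x$kruskal_wallis$left$p,
              x$kruskal_wallis$right$H, x$kruskal_wallis$right$p))
  cat("Naive Bayes 3-class:\n")
  print(as.data.frame(x$naive_bayes), digits = 3)
  invisible(x)
}
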