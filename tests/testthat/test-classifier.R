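test_that("voxel network learns separable blobs and is seed-deterministic", {
  d <- blob_data(n_per = 1000, sep = 3)
  md <- train_voxel_model(d$X, d$y, seed = 1)
  sc <- predict(md, d$X)
  expect_gte(mean((sc > 0.5) == d$y), 0.95)
  expect_true(all(sc > 0 & sc < 1))
  md2 <- train_voxel_model(d$X, d$y, seed = 1)
  expect_identical(md$W1, md2$W1)
  expect_identical(md$W2, md2$W2)
  md3 <- train_voxel_model(d$X, d$y, seed = 2)
  expect_false(identical(md$W1, md3$W1))
  expect_error(train_voxel_model(d$X, rep(1, nrow(d$X))), "both")
})

test_that("network agrees with an independent BFGS-trained net on blobs", {
  d <- blob_data(n_per = 400, sep = 3, seed = 3)
  md <- train_voxel_model(d$X, d$y, seed = 1)
  acc_sgd <- mean((predict(md, d$X) > 0.5) == d$y)
  set.seed(1)
  nn <- nnet::nnet(d$X, d$y, size = 10, entropy = TRUE, trace = FALSE,
                   maxit = 200)
  acc_bfgs <- mean((predict(nn, d$X) > 0.5) == d$y)
  expect_lt(abs(acc_sgd - acc_bfgs), 0.05)
})

test_that("cross-validated (S, s) hit the ceiling and the chance level", {
  d <- blob_data(n_per = 500, sep = 4, seed = 4)
  ss <- cv_sensitivity_specificity(d$X, d$y, folds = 5, repeats = 1, seed = 1)
  expect_gte(ss[["S"]], 0.95)
  expect_gte(ss[["s"]], 0.95)
  # labels independent of features -> both rates near 0.5
  set.seed(5)
  Xn <- matrix(rnorm(2000 * 10), ncol = 10)
  yn <- rep(c(0, 1), 1000)
  ssn <- cv_sensitivity_specificity(Xn, yn, folds = 5, repeats = 2, seed = 1)
  expect_gt(ssn[["S"]], 0.45); expect_lt(ssn[["S"]], 0.55)
  expect_gt(ssn[["s"]], 0.45); expect_lt(ssn[["s"]], 0.55)
  # determinism across calls
  ss2 <- cv_sensitivity_specificity(d$X, d$y, folds = 5, repeats = 1,
                                    seed = 1)
  expect_identical(ss, ss2)
  expect_error(cv_sensitivity_specificity(d$X[1:6, ], c(1, 1, 1, 0, 0, 0),
                                          folds = 5), "stratify")
})

test_that("prior estimation is the mean in-VOI label fraction", {
  voi <- voi_spec(c(1, 1, 1), c(4, 4, 4))           # 64 voxels
  expect_equal(estimate_prior(list(mask_n(32)), voi), 0.5)
  voi100 <- voi_spec(c(1, 1, 1), c(5, 5, 4))        # 100 voxels
  expect_equal(estimate_prior(list(mask_n(7, d = c(5, 5, 4))), voi100), 0.07)
  m1 <- mask_n(10, d = c(5, 5, 4)); m2 <- mask_n(30, d = c(5, 5, 4))
  expect_equal(estimate_prior(list(m1, m2), voi100), 0.2)
})

test_that("the Bayesian threshold matches the posterior formula", {
  expect_equal(bayes_threshold(1, 1, 0.3), 1)
  expect_equal(bayes_threshold(0.5, 0.5, 0.123), 0.123)
  expect_equal(bayes_threshold(0.9, 0.8, 0.1), 1 / 3)
  expect_error(bayes_threshold(0, 1, 0.5), "degenerate")
  tp <- threshold_params(0.9, 0.8, 0.1)
  expect_equal(tp$t, 1 / 3)
})

test_that("threshold is strictly monotone in S, s and P(H)", {
  g <- seq(0.05, 0.95, length.out = 10)
  for (s in g) for (p in g) {
    t_of_S <- vapply(g, bayes_threshold, numeric(1), s = s, prior = p)
    expect_true(all(diff(t_of_S) > 0))
  }
  for (S in g) for (p in g) {
    t_of_s <- vapply(g, function(s) bayes_threshold(S, s, p), numeric(1))
    expect_true(all(diff(t_of_s) > 0))
    t_of_p <- vapply(g, function(pp) bayes_threshold(S, p, pp), numeric(1))
    expect_true(all(diff(t_of_p) > 0))
    expect_true(all(t_of_s > 0 & t_of_s < 1))
  }
})

test_that("fusion is a convex, weight-normalized combination", {
  voi <- voi_spec(c(1, 1, 1), c(2, 2, 1))
  m1 <- score_map(rep(0.2, 4), voi)
  m2 <- score_map(rep(0.6, 4), voi)
  f <- fuse_scores(list(m1, m2), c(1, 3))
  expect_equal(as.vector(f$data), rep(0.5, 4))
  # identical maps, any weights
  expect_equal(fuse_scores(list(m1, m1), c(0.3, 0.9))$data, m1$data)
  # single atlas unchanged
  expect_equal(fuse_scores(list(m2), 0.4)$data, m2$data)
  # bounded by voxelwise min/max
  set.seed(6)
  maps <- lapply(1:4, function(i) score_map(runif(4), voi))
  w <- runif(4)
  fz <- fuse_scores(maps, w)
  lo <- pmin(maps[[1]]$data, maps[[2]]$data, maps[[3]]$data, maps[[4]]$data)
  hi <- pmax(maps[[1]]$data, maps[[2]]$data, maps[[3]]$data, maps[[4]]$data)
  expect_true(all(fz$data >= lo - 1e-12 & fz$data <= hi + 1e-12))
  expect_error(fuse_scores(list(m1, m2), c(-1, 0)), "positive")
})

test_that("binarize uses a strict 'exceeds' rule", {
  voi <- voi_spec(c(1, 1, 1), c(3, 1, 1))
  m <- score_map(c(0.2, 0.5, 0.9), voi)
  expect_equal(sum(binarize(m, 0.4)$data), 2)
  expect_equal(sum(binarize(m, 0.5)$data), 1)   # score == t stays background
  expect_equal(sum(binarize(m, 0)$data), 3)
})
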