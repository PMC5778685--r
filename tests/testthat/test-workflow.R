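test_that("configuration: defaults, overrides, unknown keys, round-trip", {
  # empty file -> all defaults
  f <- tempfile(fileext = ".yaml")
  writeLines("", f)
  expect_equal(load_config(f), default_config())

  # partial override keeps everything else at default
  writeLines(c("seed: 7", "classifier:", "  m_atlases: 4"), f)
  cfg <- load_config(f)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$classifier$m_atlases, 4)
  expect_equal(cfg$voi$padding, default_config()$voi$padding)

  # unknown key rejected with its key path
  writeLines(c("classifier:", "  atlas_cont: 3"), f)
  expect_error(load_config(f), "atlas_cont")

  # save/load round-trip (YAML and JSON)
  cfg2 <- default_config(); cfg2$seed <- 99L; cfg2$voi$padding <- 3
  fy <- tempfile(fileext = ".yaml"); fj <- tempfile(fileext = ".json")
  save_config(cfg2, fy); save_config(cfg2, fj)
  expect_equal(load_config(fy), cfg2)
  expect_equal(load_config(fj), cfg2)
  expect_error(load_config(tempfile(fileext = ".yaml")), "not found")
})

test_that("simulate stage writes phantoms and a cohort table", {
  out <- file.path(tempdir(), "hippmas-sim")
  unlink(out, recursive = TRUE)
  cfg <- default_config()
  cfg$simulate$n_atlas <- 2L; cfg$simulate$n_test <- 1L
  cfg$simulate$shape <- c(32L, 32L, 32L)
  cfg$simulate$volume_mean <- 400   # small hippocampi fit the small grid
  res <- run_pipeline("simulate", cfg, out_dir = out)
  expect_equal(res$status, 0L)
  expect_true(file.exists(file.path(out, "atlas_01.nii.gz")))
  expect_true(file.exists(file.path(out, "atlas_02_mask_l.nii.gz")))
  expect_true(file.exists(file.path(out, "test_01.nii.gz")))
  expect_true(file.exists(file.path(out, "cohort.csv")))
  expect_true(file.exists(file.path(out, "log_simulate.json")))
  co <- read.csv(file.path(out, "cohort.csv"))
  expect_equal(nrow(co), 456 * 4)
  # byte-identical reruns of the CSV artifact
  md5 <- tools::md5sum(file.path(out, "cohort.csv"))
  run_pipeline("simulate", cfg, out_dir = out)
  expect_identical(tools::md5sum(file.path(out, "cohort.csv")), md5)
  # the log records the seed
  log <- jsonlite::read_json(file.path(out, "log_simulate.json"))
  expect_equal(log$seed, cfg$seed)
})

test_that("segment without a trained atlas set names the missing artifact", {
  out <- file.path(tempdir(), "hippmas-noset")
  unlink(out, recursive = TRUE)
  expect_error(run_pipeline("segment", default_config(), out_dir = out),
               "atlas_set.*train")
  expect_error(run_pipeline("diagnose", default_config(), out_dir = out),
               "cohort")
})

test_that("diagnose stage writes a complete JSON report", {
  out <- file.path(tempdir(), "hippmas-diag")
  unlink(out, recursive = TRUE)
  dir.create(out, recursive = TRUE)
  co <- make_longitudinal(cohort_spec(seed = 5))
  write.csv(as.data.frame(co), file.path(out, "cohort.csv"),
            row.names = FALSE)
  cfg <- default_config()
  cfg$diagnostics$n_boot <- 50L
  cfg$diagnostics$nb_rounds <- 3L
  res <- run_pipeline("diagnose", cfg, out_dir = out)
  expect_equal(res$status, 0L)
  rep <- jsonlite::read_json(file.path(out, "report.json"),
                             simplifyVector = TRUE)
  expect_true(all(c("precision", "aging_model", "auc", "kruskal_wallis",
                    "naive_bayes") %in% names(rep)))
  expect_equal(rep$aging_model$left$n, 145)
  expect_true(all(rep$auc$auc > 0.5))
  # reproducibility: identical bytes on rerun
  md5 <- tools::md5sum(file.path(out, "report.json"))
  run_pipeline("diagnose", cfg, out_dir = out)
  expect_identical(tools::md5sum(file.path(out, "report.json")), md5)
})

test_that("the full chain runs end-to-end on a miniature problem", {
  out <- file.path(tempdir(), "hippmas-chain")
  unlink(out, recursive = TRUE)
  cfg <- default_config()
  cfg$simulate$n_atlas <- 3L; cfg$simulate$n_test <- 1L
  cfg$simulate$shape <- c(40L, 40L, 40L)
  cfg$simulate$volume_mean <- 650; cfg$simulate$volume_sd <- 40
  cfg$template$iterations <- 1L
  cfg$classifier$m_atlases <- 3L
  cfg$classifier$cv_repeats <- 1L
  cfg$classifier$cv_max <- 2000L
  cfg$classifier$epochs <- 40L
  cfg$diagnostics$n_boot <- 20L; cfg$diagnostics$nb_rounds <- 2L
  for (cmd in c("simulate", "template", "train", "segment", "diagnose")) {
    res <- run_pipeline(cmd, cfg, out_dir = out)
    expect_equal(res$status, 0L)
  }
  vols <- read.csv(file.path(out, "volumes.csv"))
  expect_equal(nrow(vols), 2)            # one test subject, two sides
  expect_true(all(vols$volume_mm3 > 0))
  expect_true(file.exists(file.path(out, "mask_test_01_left.nii.gz")))
  # segmentation masks land in a plausible volume range for the generator
  expect_true(all(vols$volume_mm3 > 200 & vols$volume_mm3 < 2000))
})
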