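#' Run a pipeline stage
#'
#' Command-line-style orchestration of the pipeline, one artifact-producing
#' stage at a time. Every stage writes its outputs plus a machine-readable
#' `log_<command>.json` (seeds consumed, configuration, per-stage timing)
#' under the output directory; re-running a stage with the same
#' configuration and seed reproduces its CSV/JSON outputs byte-identically.
#'
#' Stages and their artifacts:
#' \describe{
#'   \item{simulate}{atlas and test phantoms with ground-truth masks
#'     (`atlas_*.nii.gz`, `test_*.nii.gz`, `*_mask_{l,r}.nii.gz`) and a
#'     longitudinal cohort table `cohort.csv`.}
#'   \item{template}{`template.nii.gz` built from the atlas scans.}
#'   \item{train}{a serialized atlas set under `atlas_set/` (requires
#'     simulate).}
#'   \item{segment}{`mask_<id>_{left,right}.nii.gz` and `volumes.csv`
#'     (requires train).}
#'   \item{diagnose}{`report.json` with the full volumetric diagnostics
#'     (requires `cohort.csv` from simulate, or an external cohort table).}
#' }
#'
#' @param command one of `"simulate"`, `"template"`, `"train"`,
#'   `"segment"`, `"diagnose"`.
#' @param config a [default_config()] list (see [load_config()]).
#' @param out_dir output directory; defaults to `config$paths$out_dir`.
#' @param verbose print progress.
#' @return Invisibly, a list with `status` (0 on success) and `artifacts`
#'   (paths written). Missing prerequisites raise an error naming the
#'   missing artifact.
#' @export
run_pipeline <- function(command = c("simulate", "template", "train",
                                     "segment", "diagnose"),
                         config = default_config(), out_dir = NULL,
                         verbose = FALSE) {
  command <- match.arg(command)
  if (is.null(out_dir)) out_dir <- config$paths$out_dir
  if (is.null(out_dir)) stop("no output directory: set paths$out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(...)
  artifacts <- switch(command,
    simulate = stage_simulate(config, out_dir, say),
    template = stage_template(config, out_dir, say),
    train = stage_train(config, out_dir, say),
    segment = stage_segment(config, out_dir, say),
    diagnose = stage_diagnose(config, out_dir, say))
  log <- list(command = command, seed = config$seed,
              config = unclass(config),
              elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                              units = "secs")),
              artifacts = artifacts)
  logp <- file.path(out_dir, paste0("log_", command, ".json"))
  jsonlite::write_json(log, logp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(status = 0L, artifacts = c(artifacts, logp)))
}

require_artifact <- function(path, hint) {
  if (!file.exists(path))
    stop("missing prerequisite artifact: ", path, " (run `", hint,
         "` first)")
  path
}

phantom_paths <- function(out_dir, kind, i) {
  pre <- file.path(out_dir, sprintf("%s_%02d", kind, i))
  c(image = paste0(pre, ".nii.gz"), left = paste0(pre, "_mask_l.nii.gz"),
    right = paste0(pre, "_mask_r.nii.gz"))
}

stage_simulate <- function(config, out_dir, say) {
  sim <- config$simulate
  seed <- config$seed
  arts <- character(0)
  write_set <- function(kind, n, seed0) {
    for (i in seq_len(n)) {
      set.seed(seed0 + i)
      vols <- rnorm(2, sim$volume_mean, sim$volume_sd)
      ph <- make_phantom(phantom_spec(
        shape = sim$shape, volume_left = vols[1], volume_right = vols[2],
        noise_sd = sim$noise_sd, bias_amplitude = sim$bias_amplitude,
        max_translation = sim$max_translation,
        max_rotation_deg = sim$max_rotation_deg, seed = seed0 + i))
      p <- phantom_paths(out_dir, kind, i)
      write_volume(ph$image, p[["image"]])
      write_volume(ph$mask_left, p[["left"]])
      write_volume(ph$mask_right, p[["right"]])
      arts <<- c(arts, p)
      say("wrote ", p[["image"]])
    }
  }
  write_set("atlas", sim$n_atlas, seed * 100L)
  write_set("test", sim$n_test, seed * 100L + 50L)
  cohort <- make_longitudinal(cohort_spec(seed = seed))
  cp <- file.path(out_dir, "cohort.csv")
  write.csv(as.data.frame(cohort), cp, row.names = FALSE)
  arts <- c(arts, cp)
  arts
}

read_atlas_dir <- function(config, out_dir) {
  n <- config$simulate$n_atlas
  scans <- masks_l <- masks_r <- vector("list", n)
  for (i in seq_len(n)) {
    p <- phantom_paths(out_dir, "atlas", i)
    require_artifact(p[["image"]], "simulate")
    scans[[i]] <- read_volume(p[["image"]])
    masks_l[[i]] <- as_mask(read_volume(p[["left"]]))
    masks_r[[i]] <- as_mask(read_volume(p[["right"]]))
  }
  list(scans = scans, masks_l = masks_l, masks_r = masks_r)
}

stage_template <- function(config, out_dir, say) {
  at <- read_atlas_dir(config, out_dir)
  pre <- lapply(at$scans, preprocess_scan, config = config)
  templ <- build_template(pre, iterations = config$template$iterations,
                          levels = config$register$levels,
                          maxit = config$register$maxit)
  tp <- file.path(out_dir, "template.nii.gz")
  write_volume(templ$volume, tp, datatype = "double")
  say("wrote ", tp)
  tp
}

stage_train <- function(config, out_dir, say) {
  at <- read_atlas_dir(config, out_dir)
  say("training atlas set (", length(at$scans), " atlases)")
  aset <- train_atlas_set(at$scans, at$masks_l, at$masks_r, config = config,
                          seed = config$seed)
  dir <- file.path(out_dir, "atlas_set")
  save_atlas_set(aset, dir)
  say("wrote ", dir)
  dir
}

stage_segment <- function(config, out_dir, say) {
  adir <- require_artifact(file.path(out_dir, "atlas_set", "atlas_set.json"),
                           "train")
  aset <- load_atlas_set(dirname(adir))
  rows <- list()
  arts <- character(0)
  for (i in seq_len(config$simulate$n_test)) {
    p <- phantom_paths(out_dir, "test", i)
    require_artifact(p[["image"]], "simulate")
    id <- sprintf("test_%02d", i)
    res <- segment_subject(read_volume(p[["image"]]), aset, config = config,
                           id = id)
    for (sd in c("left", "right")) {
      mp <- file.path(out_dir, sprintf("mask_%s_%s.nii.gz", id, sd))
      write_volume(res[[sd]]$mask, mp)
      arts <- c(arts, mp)
    }
    rows[[i]] <- tidy(res)
    say(id, ": L=", round(res$left$volume_mm3), " R=",
        round(res$right$volume_mm3), " mm^3")
  }
  vp <- file.path(out_dir, "volumes.csv")
  write.csv(as.data.frame(dplyr::bind_rows(rows)), vp, row.names = FALSE)
  c(arts, vp)
}

stage_diagnose <- function(config, out_dir, say) {
  cp <- require_artifact(file.path(out_dir, "cohort.csv"), "simulate")
  records <- tibble::as_tibble(read.csv(cp, stringsAsFactors = FALSE))
  dg <- config$diagnostics
  rep <- cohort_report(records, reference_mean = dg$reference_mean,
                       n_boot = dg$n_boot, nb_rounds = dg$nb_rounds,
                       nb_folds = dg$nb_folds, seed = config$seed)
  out <- list(
    precision = if (!is.null(rep$precision)) unclass(rep$precision),
    correlations = if (!is.null(rep$correlations))
      lapply(rep$correlations, function(m)
        list(timepoints = rownames(m), r = unname(as.data.frame(m)))),
    aging_model = lapply(rep$aging_model, function(m)
      m[c("V0", "k", "t0", "ci_k", "se_k", "se_V0", "r2", "n", "side")]),
    auc = rep$auc,
    kruskal_wallis = rep$kruskal_wallis,
    naive_bayes = rep$naive_bayes)
  rp <- file.path(out_dir, "report.json")
  jsonlite::write_json(out, rp, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  say("wrote ", rp)
  rp
}
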