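#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline, grouped by stage. Every stochastic
#' step derives its seed from the single `seed` entry, so a run is fully
#' reproducible from its configuration.
#'
#' @return A nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    simulate = list(n_atlas = 10L, n_test = 5L, shape = c(64L, 64L, 64L),
                    volume_mean = 2650.2, volume_sd = 150,
                    noise_sd = 0.02, bias_amplitude = 0.1,
                    max_translation = 3, max_rotation_deg = 5),
    preprocess = list(bias_correct = TRUE, bias_order = 2L),
    register = list(levels = 3L, maxit = 400L, nonlinear = FALSE,
                    smoothness = 1.5, nl_iterations = 20L),
    template = list(iterations = 2L),
    voi = list(padding = 2L),
    features = list(moment_sizes = c(3L, 5L, 7L, 9L), haralick_box = 5L,
                    haralick_levels = 8L, haar_sizes = c(3L, 5L, 7L, 9L),
                    standardize_voi = TRUE),
    classifier = list(hidden = 10L, lr = 0.1, epochs = 100L, batch = 32L,
                      m_atlases = 10L, cv_folds = 5L, cv_repeats = 10L,
                      cv_max = 6000L),
    diagnostics = list(reference_mean = 2650.2, n_boot = 500L,
                       nb_folds = 10L, nb_rounds = 100L),
    paths = list(template = NULL, atlas_dir = NULL, out_dir = NULL)
  ), class = "run_config")
}

#' Load a run configuration from JSON or YAML
#'
#' Values from the file override the defaults of [default_config()]; keys
#' not present fall back to their defaults, so an empty file yields the
#' all-defaults configuration. Unknown keys are rejected with an error that
#' names the offending key path.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  restore_config(raw)
}

#' @rdname load_config
#' @param values a (possibly partial) nested configuration list.
#' @export
restore_config <- function(values) {
  def <- default_config()
  merged <- merge_config(unclass(def), values, path = character(0))
  structure(merged, class = "run_config")
}

merge_config <- function(def, new, path) {
  if (is.null(new)) return(def)
  if (!is.list(new)) {
    # leaf override: keep the default's type where sensible
    return(if (is.numeric(def)) as.numeric(new) else new)
  }
  unknown <- setdiff(names(new), names(def))
  if (length(unknown) > 0)
    stop("unknown configuration key: ",
         paste(c(path, unknown[1]), collapse = "$"))
  for (k in names(new)) {
    if (is.null(new[[k]])) next
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- merge_config(def[[k]], new[[k]], c(path, k))
    } else {
      v <- new[[k]]
      if (is.list(v)) v <- unlist(v)
      def[[k]] <- if (is.numeric(def[[k]]) && !is.null(v)) as.numeric(v) else v
    }
  }
  def
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
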