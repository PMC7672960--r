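default_run_config <- function() {
  list(
    paths = list(gmv_table = NULL, cohort_dir = NULL, output_dir = "."),
    network_scheme = "proportional:0.2",
    selector = "mtfs-glasso",
    lambda_grid = seq(0, 100, by = 5),
    inner_folds = 3L,
    epsilons = as.list(default_epsilons()),
    sigma = NULL,
    gcn = list(n_hidden_layers = 5L, cheb_order = 4L, dropout = 0.01,
               learning_rate = 0.02, epochs = 500L, hidden_width = 16L),
    cv = list(n_folds = 5L, n_repeats = 5L),
    cohort = list(n_per_class = 105L, null = FALSE),
    seed = 1L
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    here <- c(path, key)
    if (!key %in% names(defaults)) {
      abort(paste0("Unknown configuration key: ",
                   paste(here, collapse = ".")),
            class = "braingcn_config_error")
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Reads a YAML configuration (or takes a list), fills every unset key
#' with its default — the standard evaluation settings: epsilon windows
#' 1/2/2 for sex/age/MMSE, lambda grid 0 to 100 in steps of 5, 5 hidden
#' layers, K = 4, dropout 0.01, learning rate 0.02, 500 epochs — and
#' rejects unknown keys by name.
#'
#' @param config Path to a YAML file, or a (possibly partial) list.
#' @return A fully-defaulted `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("Config file not found: ", config),
            class = "braingcn_config_error")
    }
    config <- yaml::read_yaml(config) %||% list()
  }
  cfg <- merge_config(default_run_config(), config)
  cfg$selector <- match.arg(cfg$selector, c("mtfs-glasso", "ttest", "lasso"))
  parse_scheme(cfg$network_scheme)
  cfg$lambda_grid <- as.numeric(unlist(cfg$lambda_grid))
  structure(cfg, class = "run_config")
}

#' Generate a cohort from a run configuration (CLI backend)
#'
#' @param config A [validate_config()] result.
#' @param directory Output directory (defaults to the config's
#'   `paths$output_dir`).
#' @param overwrite Passed to [write_cohort()].
#' @return The written manifest, invisibly.
#' @export
cli_generate <- function(config, directory = NULL, overwrite = FALSE) {
  config <- validate_config(unclass(config))
  directory <- directory %||% config$paths$output_dir
  cohort <- generate_cohort(cohort_config(
    n_per_class = config$cohort$n_per_class,
    null = isTRUE(config$cohort$null),
    seed = config$seed))
  write_cohort(cohort, directory, overwrite = overwrite)
}

#' Compute and write feature tables for a cohort directory (CLI backend)
#'
#' @param config A [validate_config()] result with `paths$cohort_dir`
#'   set.
#' @return Paths of the written GMV/SPL feature tables, invisibly.
#' @export
cli_features <- function(config) {
  config <- validate_config(unclass(config))
  cohort <- read_cohort(config$paths$cohort_dir)
  feats <- extract_features(cohort, scheme = config$network_scheme)
  out <- config$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gmv = file.path(out, "features_gmv.csv"),
             spl = file.path(out, "features_spl.csv"))
  readr::write_csv(as_tibble(feats$gmv), paths["gmv"])
  readr::write_csv(as_tibble(feats$spl), paths["spl"])
  yaml::write_yaml(list(scheme = config$network_scheme),
                   file.path(out, "features_provenance.yaml"))
  invisible(paths)
}

#' Evaluate a cohort directory end to end (CLI backend)
#'
#' Runs repeated stratified cross-validation of the full pipeline on a
#' written cohort and stores the per-fold table, the summary and a
#' provenance record under the output directory.
#'
#' @param config A [validate_config()] result with `paths$cohort_dir`
#'   set.
#' @return The `cv_report`, invisibly.
#' @export
cli_evaluate <- function(config) {
  config <- validate_config(unclass(config))
  cohort <- read_cohort(config$paths$cohort_dir)
  dataset <- as_dataset(cohort, scheme = config$network_scheme)
  report <- run_cv(
    dataset,
    plan = cv_plan(config$cv$n_folds, config$cv$n_repeats,
                   seed = config$seed),
    selector = config$selector,
    lambda_grid = config$lambda_grid,
    inner_folds = config$inner_folds,
    epsilons = unlist(config$epsilons),
    sigma = config$sigma,
    hyper = gcn_hyperparams(
      n_hidden_layers = config$gcn$n_hidden_layers,
      cheb_order = config$gcn$cheb_order,
      dropout = config$gcn$dropout,
      learning_rate = config$gcn$learning_rate,
      epochs = config$gcn$epochs,
      hidden_width = config$gcn$hidden_width,
      seed = config$seed))
  audit_leakage(report)
  out <- config$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$folds, file.path(out, "cv_folds.csv"))
  readr::write_csv(report$summary, file.path(out, "cv_summary.csv"))
  yaml::write_yaml(list(seed = config$seed, selector = config$selector,
                        n_folds = config$cv$n_folds,
                        n_repeats = config$cv$n_repeats),
                   file.path(out, "cv_provenance.yaml"))
  invisible(report)
}
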