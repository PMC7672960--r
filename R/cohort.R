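#' Configure a synthetic imaging cohort
#'
#' Describes a two-class cohort (normal controls, NC, versus early mild
#' cognitive impairment, EMCI) with the statistical structure the analysis
#' pipeline assumes: per-region grey-matter volumes (GMV) with planted
#' atrophy in a subset of regions, modular resting-state time series whose
#' within-module correlation is weakened in the EMCI class (which perturbs
#' nodal shortest path length), and phenotype marginals (sex, age, MMSE)
#' matching a typical ADNI-style EMCI/NC sample.
#'
#' @param n_per_class Subjects per class (default 105, i.e. 210 total).
#' @param n_regions Number of atlas regions (default 90).
#' @param n_timepoints Time points per resting-state series (default 130,
#'   emulating a 140-volume acquisition with the first 10 volumes dropped).
#' @param planted_regions Integer indices of regions carrying the class
#'   effect in GMV (default the first 10 regions).
#' @param gmv_effect_d Standardized mean difference (Cohen's d) of the
#'   planted GMV atrophy; EMCI volumes are shifted down by `gmv_effect_d`
#'   within-region standard deviations.
#' @param conn_modules List of integer vectors partitioning `1:n_regions`
#'   into connectivity modules (default six modules of equal size).
#' @param rho_within_nc,rho_within_emci Within-module correlation of the
#'   latent signal for each class; `rho_within_emci < rho_within_nc`
#'   weakens EMCI modules.
#' @param rho_baseline Between-module baseline correlation.
#' @param noise_sd Standard deviation of independent observation noise
#'   added to the unit-variance latent signal.
#' @param pheno_params Per-class list with elements `age_mean`, `age_sd`,
#'   `mmse_mean`, `mmse_sd`, `p_male`. Defaults follow the demographic
#'   profile of a matched EMCI/NC sample: NC age 77.1 (6.3), EMCI age
#'   76.3 (5.4); NC MMSE 29.1 (1.1), EMCI MMSE 27.5 (1.8); male fraction
#'   54/105 (NC) and 49/105 (EMCI).
#' @param gmv_mean,gmv_sd Grand mean and within-region sd of regional
#'   volumes (arbitrary cm^3-like units); per-region baseline means are
#'   drawn once around `gmv_mean`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param null If `TRUE`, zero out every planted effect: `gmv_effect_d = 0`,
#'   `rho_within_emci = rho_within_nc`, and identical phenotype
#'   distributions in both classes (so no class signal leaks through the
#'   phenotype gate of the population graph).
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_per_class = 105L,
                          n_regions = 90L,
                          n_timepoints = 130L,
                          planted_regions = 1:10,
                          gmv_effect_d = 1.0,
                          conn_modules = NULL,
                          rho_within_nc = 0.4,
                          rho_within_emci = 0.25,
                          rho_baseline = 0.05,
                          noise_sd = 0.1,
                          pheno_params = NULL,
                          gmv_mean = 10,
                          gmv_sd = 1,
                          seed = 1L,
                          null = FALSE) {
  n_per_class <- as.integer(n_per_class)
  n_regions <- as.integer(n_regions)
  n_timepoints <- as.integer(n_timepoints)
  if (is.null(pheno_params)) {
    pheno_params <- list(
      nc = list(age_mean = 77.1, age_sd = 6.3,
                mmse_mean = 29.1, mmse_sd = 1.1, p_male = 54 / 105),
      emci = list(age_mean = 76.3, age_sd = 5.4,
                  mmse_mean = 27.5, mmse_sd = 1.8, p_male = 49 / 105)
    )
  }
  if (is.null(conn_modules)) {
    n_mod <- min(6L, n_regions)
    conn_modules <- split(seq_len(n_regions),
                          rep(seq_len(n_mod), length.out = n_regions))
    conn_modules <- unname(conn_modules)
  }
  if (isTRUE(null)) {
    gmv_effect_d <- 0
    rho_within_emci <- rho_within_nc
    pheno_params$emci <- pheno_params$nc
  }

  if (n_per_class < 2L) {
    abort(paste0("`n_per_class` must be at least 2 (got ", n_per_class, ")."),
          class = "braingcn_config_error")
  }
  planted_regions <- sort(unique(as.integer(planted_regions)))
  if (length(planted_regions) &&
      (min(planted_regions) < 1L || max(planted_regions) > n_regions)) {
    abort("`planted_regions` must lie in 1..n_regions.",
          class = "braingcn_config_error")
  }
  if (!(rho_within_emci >= 0 && rho_within_emci <= rho_within_nc &&
        rho_within_nc < 1)) {
    abort("Need 0 <= rho_within_emci <= rho_within_nc < 1.",
          class = "braingcn_config_error")
  }
  covered <- sort(unlist(conn_modules))
  if (!identical(covered, seq_len(n_regions))) {
    abort("`conn_modules` must partition 1:n_regions.",
          class = "braingcn_config_error")
  }

  cfg <- structure(
    list(n_per_class = n_per_class, n_regions = n_regions,
         n_timepoints = n_timepoints, planted_regions = planted_regions,
         gmv_effect_d = gmv_effect_d, conn_modules = conn_modules,
         rho_within_nc = rho_within_nc, rho_within_emci = rho_within_emci,
         rho_baseline = rho_baseline, noise_sd = noise_sd,
         pheno_params = pheno_params, gmv_mean = gmv_mean, gmv_sd = gmv_sd,
         seed = as.integer(seed), null = isTRUE(null)),
    class = "cohort_config"
  )
  # fail fast if either class covariance is not positive definite
  for (cls in c("nc", "emci")) {
    sigma <- class_covariance(cfg, cls)
    ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
    if (!ok) {
      abort(sprintf(
        "Time-series covariance for class %s (rho_within = %.3f, rho_baseline = %.3f) is not positive definite.",
        toupper(cls),
        if (cls == "nc") rho_within_nc else rho_within_emci, rho_baseline),
        class = "braingcn_config_error")
    }
  }
  cfg
}

# Block-structured latent-signal correlation matrix for one class.
class_covariance <- function(config, class = c("nc", "emci")) {
  class <- match.arg(class)
  rho_w <- if (class == "nc") config$rho_within_nc else config$rho_within_emci
  p <- config$n_regions
  sigma <- matrix(config$rho_baseline, p, p)
  for (mod in config$conn_modules) sigma[mod, mod] <- rho_w
  diag(sigma) <- 1
  sigma
}

region_names <- function(n) sprintf("region_%03d", seq_len(n))

# Deterministic per-subject seed fan-out: adding subjects never perturbs
# earlier ones, and streams stay inside 32-bit integer range.
subject_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1009) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws a two-class cohort from a [cohort_config()]: regional grey-matter
#' volumes with an additive atrophy shift of `gmv_effect_d` within-region
#' standard deviations in the planted regions of the EMCI class;
#' per-subject region-by-time series from a zero-mean Gaussian with
#' block-modular correlation (within-module correlation per class, small
#' baseline elsewhere) plus independent observation noise; and sex, age
#' and MMSE phenotypes from the per-class distributions in the config
#' (MMSE truncated to its 0-30 scale).
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list with `gmv`
#'   (tibble, `subject_id` plus one column per region), `timeseries`
#'   (named list of region-by-time matrices), `phenotypes` (tibble with
#'   `subject_id`, `sex`, `age`, `mmse`, `label`), `labels` (factor,
#'   levels NC then EMCI), and `truth` (the planted parameters).
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_class = 4, n_regions = 12,
#'                                      n_timepoints = 30,
#'                                      planted_regions = 1:3))
#' dim(coh$timeseries[[1]])
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_per_class
  p <- config$n_regions
  tt <- config$n_timepoints

  # cohort-level stream: region baseline means and cholesky factors
  base_mu <- withr::with_seed(config$seed,
    config$gmv_mean + rnorm(p, 0, 1.5))
  chol_by_class <- list(
    NC = chol(class_covariance(config, "nc")),
    EMCI = chol(class_covariance(config, "emci"))
  )

  labels <- factor(rep(c("NC", "EMCI"), each = n), levels = c("NC", "EMCI"))
  ids <- sprintf("sub-%04d", seq_len(2L * n))

  one_subject <- function(i) {
    cls <- as.character(labels[i])
    ph <- config$pheno_params[[tolower(cls)]]
    withr::with_seed(subject_seed(config$seed, i), {
      mu <- base_mu
      if (cls == "EMCI" && length(config$planted_regions)) {
        mu[config$planted_regions] <-
          mu[config$planted_regions] - config$gmv_effect_d * config$gmv_sd
      }
      gmv <- mu + rnorm(p, 0, config$gmv_sd)
      z <- matrix(rnorm(tt * p), tt, p) %*% chol_by_class[[cls]]
      ts <- t(z) + matrix(rnorm(p * tt, 0, config$noise_sd), p, tt)
      rownames(ts) <- region_names(p)
      list(
        gmv = gmv, ts = ts,
        sex = rbinom(1, 1, ph$p_male),
        age = rnorm(1, ph$age_mean, ph$age_sd),
        mmse = min(30, max(0, rnorm(1, ph$mmse_mean, ph$mmse_sd)))
      )
    })
  }

  subj <- lapply(seq_along(ids), one_subject)
  gmv <- do.call(rbind, lapply(subj, `[[`, "gmv"))
  colnames(gmv) <- region_names(p)
  gmv_tbl <- dplyr::bind_cols(tibble::tibble(subject_id = ids),
                              tibble::as_tibble(gmv))
  phen <- tibble::tibble(
    subject_id = ids,
    sex = vapply(subj, `[[`, integer(1), "sex"),
    age = vapply(subj, `[[`, numeric(1), "age"),
    mmse = vapply(subj, `[[`, numeric(1), "mmse"),
    label = as.character(labels)
  )
  ts_list <- stats::setNames(lapply(subj, `[[`, "ts"), ids)

  structure(
    list(gmv = gmv_tbl, timeseries = ts_list, phenotypes = phen,
         labels = labels,
         truth = list(planted_regions = config$planted_regions,
                      gmv_effect_d = config$gmv_effect_d,
                      rho_within_nc = config$rho_within_nc,
                      rho_within_emci = config$rho_within_emci,
                      seed = config$seed),
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$phenotypes), " subjects (",
      paste(table(x$labels), collapse = "/"), " per class), ",
      x$config$n_regions, " regions, T = ", x$config$n_timepoints, "\n",
      sep = "")
  invisible(x)
}

#' Write a cohort to its on-disk interchange layout
#'
#' Emits the three external files the readers consume: `gmv.csv`
#' (`subject_id` plus `region_001..region_NNN`), `phenotypes.csv`
#' (`subject_id, sex, age, mmse, label`), one CSV of region-by-time values
#' per subject under `timeseries/`, and a `manifest.yaml` recording the
#' file map and the planted truth parameters (including the seed, so the
#' cohort can be regenerated).
#'
#' @param cohort A [generate_cohort()] result.
#' @param directory Output directory (created if absent).
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return Invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  manifest_path <- file.path(directory, "manifest.yaml")
  if (file.exists(manifest_path) && !isTRUE(overwrite)) {
    abort(paste0("A cohort manifest already exists at ", manifest_path,
                 "; pass overwrite = TRUE to replace it."),
          class = "braingcn_io_error")
  }
  dir.create(file.path(directory, "timeseries"),
             recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$gmv, file.path(directory, "gmv.csv"))
  readr::write_csv(cohort$phenotypes, file.path(directory, "phenotypes.csv"))
  ts_files <- character(0)
  for (id in names(cohort$timeseries)) {
    f <- file.path("timeseries", paste0(id, ".csv"))
    readr::write_csv(tibble::as_tibble(cohort$timeseries[[id]],
                                       .name_repair = "minimal"),
                     file.path(directory, f), col_names = FALSE)
    ts_files[id] <- f
  }
  manifest <- list(
    format = "braingcn-cohort/1",
    gmv = "gmv.csv", phenotypes = "phenotypes.csv",
    timeseries = as.list(ts_files),
    n_regions = cohort$config$n_regions,
    truth = cohort$truth,
    config = unclass(cohort$config)
  )
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest)
}

#' Regenerate a cohort from the config recorded in its manifest
#'
#' The manifest stores the full generating configuration including the
#' seed, so a written cohort can be reproduced from scratch.
#'
#' @param directory Directory containing `manifest.yaml`.
#' @return A freshly generated `synthetic_cohort`.
#' @export
regenerate_cohort <- function(directory) {
  manifest <- yaml::read_yaml(file.path(directory, "manifest.yaml"))
  cfg <- manifest$config
  args <- cfg[intersect(names(cfg), names(formals(cohort_config)))]
  args$conn_modules <- lapply(cfg$conn_modules, as.integer)
  args$null <- FALSE  # effects are already folded into the stored fields
  generate_cohort(do.call(cohort_config, args))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing `manifest.yaml`.
#' @return A `synthetic_cohort`-shaped list (without the generating
#'   config) whose values round-trip the written cohort: identifiers
#'   bit-identically, numeric values to full double precision.
#' @export
read_cohort <- function(directory) {
  manifest <- yaml::read_yaml(file.path(directory, "manifest.yaml"))
  gmv <- read_gmv_table(file.path(directory, manifest$gmv),
                        n_regions = manifest$n_regions)
  phen <- readr::read_csv(file.path(directory, manifest$phenotypes),
                          show_col_types = FALSE)
  ts <- lapply(manifest$timeseries, function(f) {
    m <- as.matrix(readr::read_csv(file.path(directory, f),
                                   col_names = FALSE, show_col_types = FALSE))
    dimnames(m) <- list(region_names(nrow(m)), NULL)
    m
  })
  labels <- factor(phen$label, levels = c("NC", "EMCI"))
  structure(
    list(gmv = tibble::as_tibble(cbind(
           tibble::tibble(subject_id = rownames(gmv$values)),
           tibble::as_tibble(gmv$values))),
         timeseries = ts, phenotypes = phen, labels = labels,
         truth = manifest$truth),
    class = "synthetic_cohort"
  )
}
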