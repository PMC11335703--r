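# Config-driven orchestration of the full analysis: cohort input (CSV or
# synthetic), preparation, CCA, permutation inference, and a JSON + TSV
# report.

#' Build a pipeline run configuration
#'
#' @param input Either `"synthetic"` (a cohort is generated from
#'   `synthetic` below) or the path of a cohort CSV in the schema of
#'   [write_cohort()].
#' @param synthetic Named list of [latent_spec()] arguments used when
#'   `input = "synthetic"`.
#' @param roi `"NAWM"` (primary) or `"WMH"`; selects the NVU marginal
#'   defaults of a synthetic cohort and is recorded in the report.
#' @param cognition_mode `"tests13"` or `"domains3"`.
#' @param adjustment `"none"`, `"age_sex_edu"`, or
#'   `"age_sex_edu_brain_wmh"`.
#' @param missing Missing-data rule, `"complete"` or `"mean_impute"`.
#' @param n_permutations Permutation count for mode significance.
#' @param seed RNG seed for the whole run.
#' @param output_dir Directory for `report.json` and `loadings.tsv`;
#'   `NULL` writes nothing.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(input = "synthetic", synthetic = list(),
                       roi = c("NAWM", "WMH"),
                       cognition_mode = c("tests13", "domains3"),
                       adjustment = c("none", "age_sex_edu",
                                      "age_sex_edu_brain_wmh"),
                       missing = c("complete", "mean_impute"),
                       n_permutations = 1000, seed = 1L,
                       output_dir = NULL) {
  roi <- match.arg(roi)
  cognition_mode <- match.arg(cognition_mode)
  adjustment <- match.arg(adjustment)
  missing <- match.arg(missing)
  if (!identical(input, "synthetic") && !is.character(input))
    stop("input must be \"synthetic\" or a CSV path")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(input = input, synthetic = synthetic, roi = roi,
                 cognition_mode = cognition_mode, adjustment = adjustment,
                 missing = missing,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [run_config()]
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return Object of class `"run_config"`.
#' @export
load_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, cfg)
}

#' Shipped configuration presets
#'
#' Presets mirroring the analysis variants: `"main_nawm"` (primary,
#' unadjusted, 13 tests), `"adjusted"` (age, sex, education),
#' `"adjusted_full"` (additionally relative brain and WMH volume),
#' `"domains3"` (3 cognitive domain scores), `"wmh"` (WMH region NVU
#' variables).
#'
#' @param name Preset name.
#' @return Object of class `"run_config"`.
#' @export
preset_config <- function(name = c("main_nawm", "adjusted",
                                   "adjusted_full", "domains3", "wmh")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "nvucca")
  if (path == "") stop("preset not found: ", name)
  load_config(path)
}

adjustment_covariates <- function(adjustment) {
  switch(adjustment,
         none = NULL,
         age_sex_edu = c("age", "sex", "education"),
         age_sex_edu_brain_wmh = c("age", "sex", "education",
                                   "rel_brain_vol", "rel_wmh_vol"))
}

#' Run the full NVU-cognition analysis pipeline
#'
#' Executes cohort input -> score inversion -> matrix assembly
#' (exclusion filter, optional covariate residualization, missing-data
#' rule, z-scoring) -> canonical correlation analysis -> permutation
#' inference, and assembles a reproducible report. Internal identities
#' (shared variance = r^2, redundancy = variance extracted x shared
#' variance, totals = sums over modes) are verified at report time.
#' The report depends only on the configuration (including its seed),
#' so identical configs give byte-identical JSON reports.
#'
#' @param config A [run_config()] object (or a path accepted by
#'   [load_config()]).
#' @param verbose Log stage boundaries and subject counts.
#' @return The report (list), invisibly if files were written. Elements:
#'   `settings`, `n` (subject accounting), `modes` (per-mode r, r^2,
#'   Wilks lambda, p, variance extracted, redundancies), `totals`,
#'   `loadings` (`x`, `y`).
#' @export
#' @examples
#' cfg <- run_config(synthetic = list(seed = 2), n_permutations = 199)
#' rep <- run_pipeline(cfg, verbose = FALSE)
#' rep$modes$r[1]
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  if (identical(config$input, "synthetic")) {
    args <- config$synthetic
    if (is.null(args$seed)) args$seed <- config$seed
    if (is.null(args$roi)) args$roi <- config$roi
    cohort <- generate_cohort(do.call(latent_spec, args))$cohort
    say("generated synthetic cohort: ", nrow(cohort), " subjects")
  } else {
    cohort <- read_cohort(config$input)
    say("read cohort: ", nrow(cohort), " subjects from ", config$input)
  }
  cohort <- invert_scores(cohort)
  mats <- build_matrices(cohort, mode = config$cognition_mode,
                         adjust = adjustment_covariates(config$adjustment),
                         missing = config$missing)
  say("matrices: n = ", mats$n_effective, " (", mats$n_excluded,
      " excluded, ", mats$n_missing_dropped, " dropped for missingness)")
  fit <- nvu_cca(mats)
  perm <- permutation_test(fit, B = config$n_permutations,
                           seed = config$seed)
  say("CCA: ", length(fit$r), " modes, r1 = ", round(fit$r[1], 3),
      ", p1 = ", round(perm$p_values[1], 4))
  K <- length(fit$r)
  report <- list(
    settings = list(
      input = if (identical(config$input, "synthetic")) "synthetic"
              else config$input,
      roi = config$roi, cognition_mode = config$cognition_mode,
      adjustment = config$adjustment, missing = config$missing,
      n_permutations = config$n_permutations, seed = config$seed),
    n = list(input = nrow(cohort), excluded = mats$n_excluded,
             missing_dropped = mats$n_missing_dropped,
             effective = mats$n_effective),
    modes = data.frame(
      mode = seq_len(K),
      r = fit$r,
      shared_var = fit$shared_var,
      wilks_lambda = perm$lambda_obs,
      p = perm$p_values,
      var_extracted_x = fit$var_extracted_x,
      var_extracted_y = fit$var_extracted_y,
      redundancy_x_given_y = fit$redundancy_x_given_y,
      redundancy_y_given_x = fit$redundancy_y_given_x),
    totals = list(redundancy_x_given_y = fit$total_redundancy_x,
                  redundancy_y_given_x = fit$total_redundancy_y),
    loadings = list(x = as.data.frame(fit$Lx), y = as.data.frame(fit$Ly)))
  check_report_identities(report)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    write_loadings_tsv(fit, file.path(config$output_dir, "loadings.tsv"))
    say("report written to ", config$output_dir)
    return(invisible(report))
  }
  report
}

# Internal identities checked at write time.
check_report_identities <- function(report, tol = 1e-10) {
  m <- report$modes
  stopifnot(
    max(abs(m$shared_var - m$r^2)) < tol,
    max(abs(m$redundancy_x_given_y - m$var_extracted_x * m$r^2)) < tol,
    max(abs(m$redundancy_y_given_x - m$var_extracted_y * m$r^2)) < tol,
    abs(report$totals$redundancy_x_given_y -
          sum(m$redundancy_x_given_y)) < tol,
    abs(report$totals$redundancy_y_given_x -
          sum(m$redundancy_y_given_x)) < tol)
  invisible(TRUE)
}

# Loadings per variable per mode, long TSV (variable, set, mode, loading).
write_loadings_tsv <- function(fit, path) {
  long <- function(L, set) {
    data.frame(variable = rep(rownames(L), ncol(L)), set = set,
               mode = rep(seq_len(ncol(L)), each = nrow(L)),
               loading = as.vector(L))
  }
  tab <- rbind(long(fit$Lx, "nvu"), long(fit$Ly, "cognition"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
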