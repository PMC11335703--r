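# Cohort preparation: interference scores, score inversion, sample-based
# z scores, domain composites, covariate residualization, and assembly of
# the standardized matrices fed to the CCA.

#' Trail Making Test interference score
#'
#' Time of part B minus time of part A (seconds). A negative value
#' (faster on B) is unusual but valid data.
#'
#' @param time_B,time_A Completion times in seconds, > 0.
#' @return Interference score in seconds.
#' @export
tmt_interference <- function(time_B, time_A) {
  if (any(time_B <= 0) || any(time_A <= 0))
    stop("TMT times must be positive")
  time_B - time_A
}

#' Stroop Color-Word Test interference score
#'
#' Time of part 3 minus the mean time of parts 1 and 2 (seconds).
#'
#' @param time_3,time_1,time_2 Completion times in seconds, > 0.
#' @return Interference score in seconds.
#' @export
scwt_interference <- function(time_3, time_1, time_2) {
  if (any(time_3 <= 0) || any(time_1 <= 0) || any(time_2 <= 0))
    stop("SCWT times must be positive")
  time_3 - (time_1 + time_2) / 2
}

#' Invert scores where higher means worse
#'
#' Negates the listed columns (timed SCWT/TMT scores by default) so that
#' a higher value always means better performance. Negation before
#' z-scoring is equivalent to flipping the sign of the z score, so the
#' choice of order cannot affect downstream results. Applying the
#' function twice restores the original table.
#'
#' @param table Cohort data.frame.
#' @param vars Column names to negate; default
#'   `cohort_variables()$invert`.
#' @return The table with listed columns negated.
#' @export
invert_scores <- function(table, vars = cohort_variables()$invert) {
  unknown <- setdiff(vars, names(table))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  for (v in vars) table[[v]] <- -table[[v]]
  table
}

#' Sample-based z transformation
#'
#' `(value - sample mean) / sample SD`, with mean and SD computed over
#' the non-missing entries (SD with the n - 1 denominator). Missing
#' entries stay missing.
#'
#' @param values Numeric vector, possibly with `NA`s; at least 2
#'   observed values with positive variance.
#' @return z scores; mean 0 and SD 1 over the observed entries.
#' @export
#' @examples
#' zscore(c(1, 2, 3))   # -1 0 1
zscore <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) stop("need at least 2 observed values")
  s <- sd(obs)
  if (s == 0) stop("zero variance: z scores undefined")
  (values - mean(obs)) / s
}

#' Cognitive domain composite scores
#'
#' Per-subject mean of the z scores of the tests in each domain. If
#' exactly one test in a domain is missing, the composite is the mean of
#' the remaining tests; with more than one missing, no reliable domain
#' score can be computed and the composite is `NA`.
#'
#' @param z_table data.frame or matrix of per-test z scores (subjects in
#'   rows); every column must appear in `domain_map`.
#' @param domain_map Named character vector mapping test name to domain
#'   name; default `cohort_variables()$domains`.
#' @return data.frame of per-domain composites (one column per domain,
#'   in the order the domains first appear in `domain_map`).
#' @export
domain_composite <- function(z_table, domain_map = cohort_variables()$domains) {
  z_table <- as.data.frame(z_table)
  unmapped <- setdiff(names(z_table), names(domain_map))
  if (length(unmapped))
    stop("unmapped test(s): ", paste(unmapped, collapse = ", "))
  domains <- unique(unname(domain_map[names(z_table)]))
  out <- lapply(domains, function(d) {
    tests <- names(z_table)[domain_map[names(z_table)] == d]
    z <- as.matrix(z_table[, tests, drop = FALSE])
    n_miss <- rowSums(is.na(z))
    comp <- rowMeans(z, na.rm = TRUE)
    comp[n_miss > 1] <- NA_real_
    comp[is.nan(comp)] <- NA_real_
    comp
  })
  setNames(as.data.frame(out), domains)
}

#' Residualize analysis variables on covariates
#'
#' Replaces each NVU and cognitive column by the residuals of its
#' ordinary-least-squares regression on an intercept plus the listed
#' covariates. Missing outcome values stay missing; covariates must be
#' complete and the design full rank. Residuals are exactly orthogonal
#' to every covariate (OLS normal equations).
#'
#' @param table Cohort data.frame.
#' @param covariate_names Covariate columns to adjust for; empty vector
#'   gives mean-centred output.
#' @param vars Columns to residualize; default the NVU + cognition sets.
#' @return The table with listed columns replaced by residuals.
#' @export
residualize <- function(table, covariate_names,
                        vars = c(cohort_variables()$nvu,
                                 cohort_variables()$cognition)) {
  vars <- intersect(vars, names(table))
  unknown <- setdiff(covariate_names, names(table))
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(table[, covariate_names, drop = FALSE]))
  if (anyNA(X)) stop("covariates must be complete")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  for (v in vars) {
    y <- table[[v]]
    ok <- !is.na(y)
    fit <- lm.fit(X[ok, , drop = FALSE], y[ok])
    res <- rep(NA_real_, length(y))
    res[ok] <- fit$residuals
    table[[v]] <- res
  }
  table
}

#' Assemble the standardized matrix pair entering CCA
#'
#' From a prepared cohort table (interference scores computed, inversion
#' already applied via [invert_scores()]) this: (1) drops
#' artefact-flagged subjects; (2) optionally residualizes all analysis
#' variables on covariates; (3) applies the missing-data rule —
#' `"complete"` (listwise deletion, default) or `"mean_impute"`
#' (single imputation by the variable mean); (4) z-scores every column.
#' In `mode = "domains3"` the 13 cognitive z scores are first collapsed
#' to 3 domain composites (see [domain_composite()]) and the composites
#' re-standardized.
#'
#' @param table Cohort data.frame with the columns of
#'   [cohort_variables()].
#' @param mode `"tests13"` (Y is n x 13) or `"domains3"` (Y is n x 3).
#' @param adjust Character vector of covariates to residualize on;
#'   `NULL` for the unadjusted analysis.
#' @param missing `"complete"` or `"mean_impute"`.
#' @return Object of class `"cca_matrices"`: list with standardized
#'   matrices `X` (n x 5) and `Y`, `n_effective`, and counts of dropped
#'   subjects (`n_excluded`, `n_missing_dropped`).
#' @export
#' @examples
#' cohort <- invert_scores(generate_cohort(latent_spec(seed = 3))$cohort)
#' mats <- build_matrices(cohort)
#' dim(mats$X); dim(mats$Y)
build_matrices <- function(table, mode = c("tests13", "domains3"),
                           adjust = NULL,
                           missing = c("complete", "mean_impute")) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  vars <- cohort_variables()
  needed <- c(vars$nvu, vars$cognition)
  absent <- setdiff(needed, names(table))
  if (length(absent))
    stop("table lacks column(s): ", paste(absent, collapse = ", "))
  n0 <- nrow(table)
  if (!is.null(table$excluded)) table <- table[!table$excluded, , drop = FALSE]
  n_excluded <- n0 - nrow(table)
  if (!is.null(adjust) && length(adjust) > 0)
    table <- residualize(table, adjust, vars = needed)
  X <- as.matrix(table[, vars$nvu, drop = FALSE])
  Y <- as.matrix(table[, vars$cognition, drop = FALSE])
  if (mode == "domains3") {
    zY <- as.data.frame(apply(Y, 2, zscore))
    Y <- as.matrix(domain_composite(zY, vars$domains))
  }
  if (missing == "mean_impute") {
    impute <- function(M) apply(M, 2, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE); col })
    X <- impute(X); Y <- impute(Y)
  }
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  n_missing_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  Y <- Y[ok, , drop = FALSE]
  n <- nrow(X)
  if (n <= ncol(X) + ncol(Y))
    stop("CCA ill-posed: ", n, " subjects for ", ncol(X) + ncol(Y),
         " variables after filtering")
  X <- apply(X, 2, zscore)
  Y <- apply(Y, 2, zscore)
  structure(list(X = X, Y = Y, n_effective = n, n_excluded = n_excluded,
                 n_missing_dropped = n_missing_dropped,
                 mode = mode, adjust = adjust, missing = missing),
            class = "cca_matrices")
}

#' @export
print.cca_matrices <- function(x, ...) {
  cat(sprintf(
    "Standardized CCA matrices: n = %d (excluded %d, missing-dropped %d)\n",
    x$n_effective, x$n_excluded, x$n_missing_dropped))
  cat(sprintf("  X: %d x %d   Y: %d x %d (%s%s)\n",
              nrow(x$X), ncol(x$X), nrow(x$Y), ncol(x$Y), x$mode,
              if (is.null(x$adjust)) "" else
                paste0(", adjusted for ", paste(x$adjust, collapse = "+"))))
  invisible(x)
}
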