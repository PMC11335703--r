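# Latent-variable cohort simulator: plants a specifiable canonical
# correlation structure between the NVU and cognition variable sets.

#' Specify the latent structure of a synthetic cohort
#'
#' Builds and validates the specification consumed by [generate_cohort()].
#' The generator draws K latent standard-normal pairs (u_k, v_k) with
#' cross-pair independence; the NVU set is `X = u %*% t(loadings_x) +
#' noise` and the cognition set `Y = v %*% t(loadings_y) + noise`, after
#' which each column is rescaled to the requested marginal mean/SD
#' (an affine map, so it cannot change canonical correlations).
#'
#' Because the loading matrices have orthonormal columns and the noise is
#' homoscedastic within a set, the population canonical correlations of
#' the generated data are exactly `rho`: internally the latent-pair
#' correlation is inflated to `rho * sqrt((1 + noise_sd_x^2) *
#' (1 + noise_sd_y^2))` to cancel the attenuation by measurement noise.
#' An error is raised if the requested `rho` is unattainable at the
#' requested noise level. If per-variable noise SD vectors are supplied
#' the planting is approximate.
#'
#' @param n_subjects Number of subjects (rows), before exclusion.
#' @param rho Planted canonical correlations, non-increasing, in \[0, 1).
#'   Length K must not exceed `min(p, q)`.
#' @param loadings_x,loadings_y Latent-to-observed weight matrices
#'   (p x K and q x K) with orthonormal columns; defaults put every
#'   variable on the first latent with equal weight and fill further
#'   modes with an orthonormal completion.
#' @param noise_sd_x,noise_sd_y Residual SD per variable (scalar or
#'   vector), > 0.
#' @param marginal_means,marginal_sds Target marginal moments for the
#'   p + q observed variables, in reported units; defaults from
#'   [nvu_marginals()] and [cognition_marginals()].
#' @param missing_rate Probability that a cognitive score cell is missing
#'   (missing completely at random, cognitive tests only).
#' @param n_excluded Number of subjects flagged for imaging artefacts.
#' @param roi Region of interest whose NVU marginal moments are used for
#'   the defaults, `"NAWM"` or `"WMH"`.
#' @param seed RNG seed (integer).
#' @return An object of class `"latent_spec"`.
#' @export
#' @examples
#' spec <- latent_spec(n_subjects = 80, rho = c(0.73, 0, 0, 0, 0),
#'                     n_excluded = 7, seed = 42)
latent_spec <- function(n_subjects = 80,
                        rho = c(0.73, 0, 0, 0, 0),
                        loadings_x = NULL,
                        loadings_y = NULL,
                        noise_sd_x = 0.5,
                        noise_sd_y = 0.5,
                        marginal_means = NULL,
                        marginal_sds = NULL,
                        missing_rate = 0.005,
                        n_excluded = 7,
                        roi = c("NAWM", "WMH"),
                        seed = 1L) {
  roi <- match.arg(roi)
  vars <- cohort_variables()
  p <- length(vars$nvu)
  q <- length(vars$cognition)
  K <- length(rho)
  if (K < 1 || K > min(p, q))
    stop("length(rho) must be between 1 and min(p, q) = ", min(p, q))
  if (any(rho < 0) || any(rho >= 1))
    stop("all planted canonical correlations must lie in [0, 1)")
  if (any(diff(rho) > 1e-12))
    stop("rho must be non-increasing")
  if (is.null(loadings_x)) loadings_x <- default_loadings(p, K)
  if (is.null(loadings_y)) {
    loadings_y <- default_loadings(q, K)
    # the latent represents cognitive ability: timed (to-be-inverted)
    # scores load negatively on the raw scale; row sign flips preserve
    # column orthonormality and the planted correlations
    flip <- vars$cognition %in% vars$invert
    loadings_y[flip, ] <- -loadings_y[flip, ]
  }
  check_orthonormal(loadings_x, p, K, "loadings_x")
  check_orthonormal(loadings_y, q, K, "loadings_y")
  if (any(noise_sd_x <= 0) || any(noise_sd_y <= 0))
    stop("noise SDs must be positive")
  if (!length(noise_sd_x) %in% c(1L, p) || !length(noise_sd_y) %in% c(1L, q))
    stop("noise SD must be a scalar or one value per variable")
  defaults <- rbind(nvu_marginals(roi), cognition_marginals())
  if (is.null(marginal_means)) marginal_means <- defaults$mean
  if (is.null(marginal_sds)) marginal_sds <- defaults$sd
  if (length(marginal_means) != p + q || length(marginal_sds) != p + q)
    stop("marginal moments must have one entry per observed variable (",
         p + q, ")")
  if (any(marginal_sds <= 0)) stop("marginal SDs must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_excluded < 0 || n_excluded >= n_subjects)
    stop("n_excluded must lie in [0, n_subjects)")
  # attenuation by within-set noise; cancelled so population canonical
  # correlations equal rho exactly (homoscedastic case)
  atten <- sqrt((1 + mean(noise_sd_x)^2) * (1 + mean(noise_sd_y)^2))
  if (any(rho * atten >= 1))
    stop("planted rho unattainable at this noise level: need rho * ",
         signif(atten, 4), " < 1")
  structure(
    list(n_subjects = as.integer(n_subjects), rho = rho,
         loadings_x = loadings_x, loadings_y = loadings_y,
         noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
         marginal_means = marginal_means, marginal_sds = marginal_sds,
         missing_rate = missing_rate, n_excluded = as.integer(n_excluded),
         roi = roi, seed = as.integer(seed), latent_cor = rho * atten),
    class = "latent_spec")
}

# Deterministic orthonormal p x K basis whose first column is the equal
# 1/sqrt(p) loading on every variable.
default_loadings <- function(p, K) {
  base <- cbind(rep(1, p), diag(p)[, seq_len(K - 1), drop = FALSE])
  Q <- qr.Q(qr(base))[, seq_len(K), drop = FALSE]
  # fix column signs so the first non-tiny entry is positive
  for (k in seq_len(K)) {
    j <- which(abs(Q[, k]) > 1e-8)[1]
    if (Q[j, k] < 0) Q[, k] <- -Q[, k]
  }
  Q
}

check_orthonormal <- function(L, p, K, name) {
  if (!is.matrix(L) || nrow(L) != p || ncol(L) != K)
    stop(name, " must be a ", p, " x ", K, " matrix")
  if (max(abs(crossprod(L) - diag(K))) > 1e-8)
    stop(name, " must have orthonormal columns")
}

#' Generate a synthetic cohort with planted canonical structure
#'
#' Draws a subject-by-variable cohort table whose population canonical
#' correlations between the NVU set and the cognition set equal
#' `spec$rho` (see [latent_spec()] for the construction). Covariates
#' (age, sex, education on the 7-level Verhage scale, relative brain and
#' WMH volumes) are drawn independently of the latent structure, so that
#' covariate adjustment leaves the canonical correlations essentially
#' unchanged. Missingness is injected completely at random into the
#' cognitive scores; `n_excluded` randomly chosen subjects carry an
#' imaging-artefact exclusion flag.
#'
#' The same spec (including seed) always yields the identical table.
#'
#' @param spec A [latent_spec()] object.
#' @return A list with elements
#'   \describe{
#'     \item{cohort}{data.frame: `subject_id`, 5 NVU columns, 13
#'       cognitive columns, 5 covariates, logical `excluded`.}
#'     \item{truth}{list: planted `rho`, `loadings_x`, `loadings_y`, the
#'       internal latent correlations after noise calibration, and
#'       `mri_params`, per-subject ground-truth MRI parameters in SI-ish
#'       units (Ki in 1/min, vp, f/f_int as fractions, diffusivities in
#'       mm^2/s) consistent with the cohort's NVU columns.}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(latent_spec(seed = 7))
#' nrow(cohort$cohort)   # 80
#' sum(cohort$cohort$excluded)  # 7
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "latent_spec"))
  vars <- cohort_variables()
  p <- length(vars$nvu); q <- length(vars$cognition)
  n <- spec$n_subjects; K <- length(spec$rho)
  with_seed(spec$seed, {
    a <- spec$latent_cor
    u <- matrix(rnorm(n * K), n, K)
    v <- u %*% diag(a, K) +
      matrix(rnorm(n * K), n, K) %*% diag(sqrt(1 - a^2), K)
    X <- u %*% t(spec$loadings_x) +
      sweep(matrix(rnorm(n * p), n, p), 2, rep_len(spec$noise_sd_x, p), `*`)
    Y <- v %*% t(spec$loadings_y) +
      sweep(matrix(rnorm(n * q), n, q), 2, rep_len(spec$noise_sd_y, q), `*`)
    # rescale columns to target moments using population moments of the
    # generating process (affine, hence canonical-correlation preserving)
    pop_sd_x <- sqrt(rowSums(spec$loadings_x^2) + rep_len(spec$noise_sd_x, p)^2)
    pop_sd_y <- sqrt(rowSums(spec$loadings_y^2) + rep_len(spec$noise_sd_y, q)^2)
    mm <- spec$marginal_means; ms <- spec$marginal_sds
    X <- sweep(sweep(X, 2, pop_sd_x, `/`), 2, ms[seq_len(p)], `*`)
    X <- sweep(X, 2, mm[seq_len(p)], `+`)
    Y <- sweep(sweep(Y, 2, pop_sd_y, `/`), 2, ms[p + seq_len(q)], `*`)
    Y <- sweep(Y, 2, mm[p + seq_len(q)], `+`)
    colnames(X) <- vars$nvu
    colnames(Y) <- vars$cognition
    if (spec$missing_rate > 0) {
      mask <- matrix(runif(n * q) < spec$missing_rate, n, q)
      Y[mask] <- NA_real_
    }
    excluded <- rep(FALSE, n)
    excluded[sample.int(n, spec$n_excluded)] <- TRUE
    covs <- data.frame(
      age = rnorm(n, 70.2, 10.8),
      sex = rbinom(n, 1, 0.411),
      education = pmin(7L, pmax(1L, as.integer(round(rnorm(n, 4.5, 1.1))))),
      rel_brain_vol = rnorm(n, 0.75, 0.04),
      rel_wmh_vol = exp(rnorm(n, log(0.0095), 0.8)))
    cohort <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         X, Y, covs, excluded = excluded,
                         stringsAsFactors = FALSE)
    truth <- list(
      rho = spec$rho,
      loadings_x = spec$loadings_x,
      loadings_y = spec$loadings_y,
      latent_cor = spec$latent_cor,
      mri_params = data.frame(
        subject_id = cohort$subject_id,
        Ki = X[, "Ki"] * 1e-4,          # 1/min
        vp = 0.01,
        f = X[, "f"] / 100,
        Dstar = X[, "Dstar"] * 1e-2,    # mm^2/s
        f_int = X[, "f_int"] / 100,
        D_int = 2.5e-3,
        D_par = 0.7e-3))
    list(cohort = cohort, truth = truth)
  })
}

#' Write / read a cohort table as CSV (+ JSON truth sidecar)
#'
#' @param x The list returned by [generate_cohort()], or a bare cohort
#'   data.frame.
#' @param path CSV path; the truth sidecar (if present) is written next
#'   to it with extension `.truth.json`.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort data.frame (with logical `excluded`).
#' @export
write_cohort <- function(x, path) {
  cohort <- if (is.data.frame(x)) x else x$cohort
  write.csv(cohort, path, row.names = FALSE)
  if (!is.data.frame(x) && !is.null(x$truth)) {
    sidecar <- sub("\\.csv$", "", path)
    jsonlite::write_json(x$truth, paste0(sidecar, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", cohort_variables()$nvu,
              cohort_variables()$cognition, "excluded")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort CSV lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  cohort$excluded <- as.logical(cohort$excluded)
  cohort
}
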