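# DCE-MRI quantification: graphical Patlak estimation of the BBB
# leakage rate and histogram-method leakage volume.

#' Graphical Patlak fit of a concentration-time curve
#'
#' Linearises the unidirectional-transfer model by plotting
#' `y = Ct/Cp` against the "Patlak time" `x = (integral_0^t Cp) / Cp`
#' and fitting ordinary least squares over the chosen window. The slope
#' is the blood-brain barrier leakage rate Ki (1/min) and the intercept
#' the plasma volume fraction vp. The cumulative integral uses the
#' trapezoid rule on the sample grid. Points with `Cp <= cp_tol` are
#' unusable (division blow-up) and dropped.
#'
#' Patlak linearity assumes post-bolus quasi-equilibrium, so the window
#' conventionally starts after bolus arrival; by default all usable
#' samples are taken, and `fit_window` restricts to an index range.
#'
#' @param curve data.frame with columns `t` (min, strictly increasing),
#'   `Ct`, `Cp` — e.g. from [simulate_dce_curve()].
#' @param fit_window Optional integer indices (into the rows of `curve`)
#'   delimiting the fit window; default all samples.
#' @param cp_tol Positivity tolerance on Cp; samples at or below it are
#'   excluded.
#' @return Object of class `"patlak_fit"`: list with `Ki` (1/min), `vp`,
#'   `fit_r2`, `n_used`, and the fitted `x`/`y` points.
#' @export
#' @examples
#' curve <- simulate_dce_curve(dce_spec(Ki = 1e-3, vp = 0.02))
#' fit <- patlak_fit(curve)
#' c(fit$Ki, fit$vp)
patlak_fit <- function(curve, fit_window = NULL, cp_tol = 1e-12) {
  stopifnot(all(c("t", "Ct", "Cp") %in% names(curve)))
  t <- curve$t; Ct <- curve$Ct; Cp <- curve$Cp
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  idx <- seq_along(t)
  if (!is.null(fit_window)) idx <- intersect(idx, fit_window)
  cum <- pracma::cumtrapz(t, Cp)[, 1]
  usable <- idx[Cp[idx] > cp_tol]
  if (length(usable) < 3)
    stop("fewer than 3 usable points (Cp > ", cp_tol, ") in the window")
  x <- cum[usable] / Cp[usable]
  y <- Ct[usable] / Cp[usable]
  # centred OLS: better conditioned than the raw normal equations when
  # the Patlak time spans several orders of magnitude
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((yc - slope * xc)^2)
  ss_tot <- sum(yc^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(list(Ki = unname(slope), vp = unname(intercept),
                 fit_r2 = r2, n_used = length(usable), x = x, y = y),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat("Patlak fit:", x$n_used, "points\n")
  cat(sprintf("  Ki = %.4g /min   vp = %.4g   R^2 = %.4f\n",
              x$Ki, x$vp, x$fit_r2))
  invisible(x)
}

#' Histogram-method leakage volume from a voxel-wise Ki map
#'
#' Estimates the fraction of tissue with detectable BBB leakage. Under
#' pure noise the voxel-wise Patlak slope is symmetric about zero, so
#' the negative slopes estimate the noise distribution: they are
#' mirrored about zero and the `prob` upper quantile of that symmetric
#' sample is the noise threshold. The leakage volume VL is the fraction
#' of voxels whose Ki exceeds the threshold. By construction, pure-noise
#' input yields VL near `1 - prob` (the quantile's false-positive rate),
#' and the estimate is invariant to positive rescaling of the Ki map.
#'
#' With no negative voxels the noise distribution cannot be estimated;
#' behaviour is then explicit via `no_noise`: error (default) or use a
#' threshold of zero.
#'
#' @param ki_values Numeric vector of voxel-wise Ki estimates (1/min).
#' @param prob Upper quantile of the mirrored-noise distribution used as
#'   detection threshold; default 0.95.
#' @param no_noise `"error"` or `"zero"`: what to do when no negative
#'   values are available to estimate noise.
#' @return Object of class `"leakage_volume"`: list with `VL` (fraction
#'   in \[0,1\]), `threshold` (1/min), `n_voxels`.
#' @export
#' @examples
#' set.seed(1)
#' ki <- c(rnorm(500, 0, 1e-4), rnorm(500, 5e-4, 1e-4))
#' leakage_volume(ki)
leakage_volume <- function(ki_values, prob = 0.95,
                           no_noise = c("error", "zero")) {
  no_noise <- match.arg(no_noise)
  if (length(ki_values) == 0) stop("empty Ki vector")
  if (anyNA(ki_values)) ki_values <- ki_values[!is.na(ki_values)]
  if (length(ki_values) == 0) stop("no finite Ki values")
  if (all(ki_values < 0))
    stop("all Ki values negative: input looks inverted")
  if (prob <= 0 || prob >= 1) stop("prob must lie in (0, 1)")
  neg <- ki_values[ki_values < 0]
  if (length(neg) == 0) {
    if (no_noise == "error")
      stop("no negative Ki values: noise distribution cannot be ",
           "estimated (set no_noise = \"zero\" to threshold at 0)")
    threshold <- 0
  } else {
    mirrored <- c(neg, -neg)
    threshold <- quantile(mirrored, prob, names = FALSE)
  }
  structure(list(VL = mean(ki_values > threshold), threshold = threshold,
                 n_voxels = length(ki_values)),
            class = "leakage_volume")
}

#' @export
print.leakage_volume <- function(x, ...) {
  cat(sprintf("Leakage volume: VL = %.3f (threshold %.3g /min, %d voxels)\n",
              x$VL, x$threshold, x$n_voxels))
  invisible(x)
}

#' Mean of a parameter map over a region-of-interest mask
#'
#' @param values Numeric vector (voxel-wise parameter values).
#' @param mask Logical vector of the same length selecting at least one
#'   voxel.
#' @return Arithmetic mean over selected voxels.
#' @export
roi_mean <- function(values, mask) {
  if (length(values) != length(mask))
    stop("values and mask must have equal length")
  if (!is.logical(mask)) stop("mask must be logical")
  if (!any(mask)) stop("mask selects no voxels")
  mean(values[mask])
}
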