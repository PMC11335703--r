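# Ground-truth MRI signal simulators: Patlak-kinetics DCE concentration
# curves and three-component IVIM diffusion decay curves.

#' Default b-value scheme for IVIM simulation and fitting (s/mm^2)
#'
#' Fifteen b-values spanning the microvascular (b < 60), intermediate and
#' parenchymal diffusion regimes.
#'
#' @return Numeric vector of length 15 including b = 0.
#' @export
ivim_bvalues <- function() {
  c(0, 5, 7, 10, 15, 20, 30, 40, 50, 60, 100, 200, 400, 700, 1000)
}

#' Parametric vascular input function
#'
#' A smooth positive plasma concentration curve Cp(t): gamma-variate
#' bolus rise multiplied by a biexponential washout,
#' `Cp(t) = A * x^alpha * exp(-x/tau) / m * (w1*exp(-k1*x) +
#' w2*exp(-k2*x))` with `x = t - t0` (zero before bolus arrival) and `m`
#' normalising the gamma-variate peak to 1. Any smooth positive Cp is
#' valid input for Patlak estimation; this shape mimics a first-pass
#' bolus followed by slow clearance.
#'
#' @param t Time (minutes).
#' @param amplitude Peak scale A (mM).
#' @param arrival Bolus arrival time t0 (min).
#' @param alpha,tau Gamma-variate shape/scale of the rise.
#' @param w1,k1,w2,k2 Weights and rate constants (1/min) of the washout.
#' @return Cp(t), mM, same length as `t`.
#' @export
vif_curve <- function(t, amplitude = 5, arrival = 0.5, alpha = 2,
                      tau = 0.25, w1 = 0.6, k1 = 0.05, w2 = 0.4, k2 = 0.8) {
  x <- pmax(t - arrival, 0)
  g <- x^alpha * exp(-x / tau)
  peak <- (alpha * tau)^alpha * exp(-alpha)   # gamma-variate maximum
  amplitude * g / peak * (w1 * exp(-k1 * x) + w2 * exp(-k2 * x))
}

#' Specify a DCE concentration-curve simulation
#'
#' @param times Sample times in minutes, strictly increasing.
#' @param vif_params Named list of [vif_curve()] parameters overriding
#'   its defaults.
#' @param Ki Blood-brain barrier leakage rate (1/min), >= 0.
#' @param vp Plasma volume fraction, in \[0, 1).
#' @param noise_sd Additive Gaussian noise SD on the tissue
#'   concentration (mM); 0 for a noiseless curve.
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return Object of class `"dce_spec"`.
#' @export
dce_spec <- function(times = seq(0, 20, by = 1 / 6), vif_params = list(),
                     Ki = 3.3e-4, vp = 0.01, noise_sd = 0, seed = 1L) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (Ki < 0) stop("Ki must be non-negative")
  if (vp < 0 || vp >= 1) stop("vp must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(times = times, vif_params = vif_params, Ki = Ki, vp = vp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dce_spec")
}

#' Simulate a DCE tissue concentration curve under Patlak kinetics
#'
#' The tissue concentration is the Patlak forward model
#' `Ct(t) = vp * Cp(t) + Ki * integral_0^t Cp`, with the integral taken
#' by the trapezoid rule on the sample grid (the same quadrature used by
#' [patlak_fit()], so noiseless curves are recovered exactly), plus
#' optional additive Gaussian noise.
#'
#' @param spec A [dce_spec()] object.
#' @return data.frame with columns `t` (min), `Ct` (mM), `Cp` (mM).
#' @export
#' @examples
#' curve <- simulate_dce_curve(dce_spec(Ki = 3.3e-4, vp = 0.01))
#' patlak_fit(curve)
simulate_dce_curve <- function(spec) {
  stopifnot(inherits(spec, "dce_spec"))
  t <- spec$times
  Cp <- do.call(vif_curve, c(list(t = t), spec$vif_params))
  Ct <- spec$vp * Cp + spec$Ki * pracma::cumtrapz(t, Cp)[, 1]
  if (spec$noise_sd > 0)
    Ct <- Ct + with_seed(spec$seed, rnorm(length(t), 0, spec$noise_sd))
  data.frame(t = t, Ct = Ct, Cp = Cp)
}

#' Specify a three-component IVIM signal simulation
#'
#' @param bvalues Diffusion weightings (s/mm^2), non-negative, must
#'   include 0; default [ivim_bvalues()].
#' @param f Microvascular perfusion volume fraction (unitless), >= 0.
#' @param f_int Intermediate (interstitial/perivascular fluid) volume
#'   fraction, >= 0; `f + f_int < 1`.
#' @param Dstar Microvascular (pseudo-)diffusivity (mm^2/s).
#' @param D_int Intermediate diffusivity (mm^2/s).
#' @param D_par Parenchymal diffusivity (mm^2/s). Ordering
#'   `Dstar > D_int > D_par > 0` is required.
#' @param S0 Signal at b = 0.
#' @param snr Signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param rician If `TRUE`, magnitude (Rician) noise instead of additive
#'   Gaussian; relevant only at low SNR.
#' @param seed RNG seed used when `snr < Inf`.
#' @return Object of class `"ivim_spec"`.
#' @export
ivim_spec <- function(bvalues = ivim_bvalues(), f = 0.011, f_int = 0.093,
                      Dstar = 0.10, D_int = 2.5e-3, D_par = 0.7e-3,
                      S0 = 1, snr = Inf, rician = FALSE, seed = 1L) {
  if (any(bvalues < 0) || !any(bvalues == 0))
    stop("bvalues must be non-negative and include 0")
  if (f < 0 || f_int < 0 || f + f_int >= 1)
    stop("need f >= 0, f_int >= 0 and f + f_int < 1")
  if (!(Dstar > D_int && D_int > D_par && D_par > 0))
    stop("diffusivity ordering Dstar > D_int > D_par > 0 violated")
  if (S0 <= 0 || snr <= 0) stop("S0 and snr must be positive")
  structure(list(bvalues = bvalues, f = f, f_int = f_int, Dstar = Dstar,
                 D_int = D_int, D_par = D_par, S0 = S0, snr = snr,
                 rician = rician, seed = as.integer(seed)),
            class = "ivim_spec")
}

# Triexponential IVIM forward model.
ivim_model <- function(b, f, f_int, Dstar, D_int, D_par, S0 = 1) {
  S0 * (f * exp(-b * Dstar) + f_int * exp(-b * D_int) +
          (1 - f - f_int) * exp(-b * D_par))
}

#' Simulate a three-component IVIM diffusion decay curve
#'
#' `S(b) = S0 * (f*exp(-b*Dstar) + f_int*exp(-b*D_int) +
#' (1 - f - f_int)*exp(-b*D_par))`, with noise of SD `S0/snr` added
#' per sample (Gaussian by default; Rician if requested).
#'
#' @param spec An [ivim_spec()] object.
#' @return data.frame with columns `b` (s/mm^2) and `S`.
#' @export
#' @examples
#' sig <- simulate_ivim_signal(ivim_spec())
#' fit_ivim_3c(sig)
simulate_ivim_signal <- function(spec) {
  stopifnot(inherits(spec, "ivim_spec"))
  b <- spec$bvalues
  S <- ivim_model(b, spec$f, spec$f_int, spec$Dstar, spec$D_int,
                  spec$D_par, spec$S0)
  if (is.finite(spec$snr)) {
    sdn <- spec$S0 / spec$snr
    S <- with_seed(spec$seed, {
      if (spec$rician) {
        sqrt((S + rnorm(length(b), 0, sdn))^2 + rnorm(length(b), 0, sdn)^2)
      } else {
        S + rnorm(length(b), 0, sdn)
      }
    })
  }
  data.frame(b = b, S = S)
}
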