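# Data dictionary: canonical column names, units and reference marginal
# moments (cohort means/SDs) for the two variable sets and the covariates.

#' Variable dictionary for the NVU-cognition cohort
#'
#' Canonical column names used throughout the package: the five NVU
#' function variables, the 13 cognitive test scores with their domain
#' assignment, the covariates, and the default list of scores that are
#' inverted before analysis (tests where a higher score means worse
#' performance, i.e. timed SCWT/TMT scores).
#'
#' The cognitive battery holds 13 scores across three domains: memory
#' (RAVLT immediate recall, delayed recall, delayed recognition; digit
#' span forward), executive function (TMT and SCWT interference scores,
#' category and letter fluency, letter-number sequencing, digit span
#' backward) and psychomotor speed (TMT part A, the mean time of SCWT
#' parts 1 and 2 as a single basic-speed score, symbol-substitution
#' coding).
#'
#' @return A list with elements `nvu` (character, length 5), `cognition`
#'   (character, length 13), `domains` (named character: test -> domain),
#'   `invert` (character: scores negated by default), `covariates`
#'   (character, length 5).
#' @export
#' @examples
#' cohort_variables()$nvu
cohort_variables <- function() {
  nvu <- c("Ki", "VL", "f", "Dstar", "f_int")
  memory <- c("ravlt_immediate", "ravlt_delayed", "ravlt_recognition",
              "digit_span_forward")
  executive <- c("tmt_interference", "scwt_interference",
                 "fluency_categories", "fluency_letters",
                 "letter_number_seq", "digit_span_backward")
  speed <- c("tmt_a", "scwt_speed", "symbol_coding")
  cognition <- c(memory, executive, speed)
  domains <- setNames(
    rep(c("memory", "executive", "speed"),
        times = c(length(memory), length(executive), length(speed))),
    cognition)
  list(
    nvu = nvu,
    cognition = cognition,
    domains = domains,
    invert = c("tmt_interference", "scwt_interference", "tmt_a",
               "scwt_speed"),
    covariates = c("age", "sex", "education", "rel_brain_vol",
                   "rel_wmh_vol"))
}

#' Reference marginal moments for the NVU variables
#'
#' Cohort means and standard deviations of the five NVU function measures
#' in the units in which they are conventionally reported: Ki in
#' 1e-4/min, VL in %, f in %, D* in 1e-2 mm^2/s, f_int in %. Values are
#' available for both regions of interest: normal-appearing white matter
#' (`"NAWM"`, the primary analysis region) and white matter
#' hyperintensities (`"WMH"`).
#'
#' @param roi `"NAWM"` or `"WMH"`.
#' @return A data.frame with columns `variable`, `mean`, `sd`.
#' @export
nvu_marginals <- function(roi = c("NAWM", "WMH")) {
  roi <- match.arg(roi)
  if (roi == "NAWM") {
    data.frame(
      variable = cohort_variables()$nvu,
      mean = c(3.3, 35.7, 1.1, 10.0, 9.3),
      sd   = c(1.6, 16.5, 0.1, 0.1, 0.4))
  } else {
    data.frame(
      variable = cohort_variables()$nvu,
      mean = c(3.6, 42.0, 1.6, 9.4, 17.7),
      sd   = c(2.0, 20.1, 0.2, 0.3, 2.9))
  }
}

#' Reference marginal moments for the cognitive test scores
#'
#' Cohort means and standard deviations of the 13 cognitive scores, on
#' their raw scales (times in seconds for TMT/SCWT scores, counts
#' otherwise). The single SCWT basic-speed score is the mean time of
#' SCWT parts 1 and 2.
#'
#' @return A data.frame with columns `variable`, `mean`, `sd`.
#' @export
cognition_marginals <- function() {
  data.frame(
    variable = cohort_variables()$cognition,
    mean = c(32.1, 5.4, 11.4, 7.4,
             118.5, 87.5, 30.3, 24.8, 6.7, 5.3,
             66.1, 67.05, 42.5),
    sd   = c(10.3, 3.5, 3.2, 2.0,
             100.8, 53.0, 10.6, 12.6, 3.3, 1.7,
             34.5, 16.5, 18.7))
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
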