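---
title: "Relating neurovascular unit function to cognition: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating neurovascular unit function to cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models behind `nvucca`, the
assumptions they make, the parameters that matter, and the design
decisions taken where more than one defensible construction existed. It
is the package's methods reference; the README shows the quick tour.

## The scientific problem

In cerebral small vessel disease, the functions of the neurovascular
unit (NVU) — cerebral blood flow regulation, blood–brain barrier (BBB)
integrity, perivascular clearance — are believed to fail together, and
each is only partially visible to any single quantitative MRI marker.
The package therefore analyses the *joint* association between a
five-variable NVU set, measured per subject over a region of interest
(primary: normal-appearing white matter, NAWM), and a 13-score
neuropsychological battery:

* `Ki` — BBB leakage rate from dynamic contrast-enhanced (DCE) MRI,
  reported in 10⁻⁴ min⁻¹;
* `VL` — BBB leakage volume, % of tissue voxels with detectable leakage;
* `f` — IVIM microvascular perfusion volume fraction, %;
* `Dstar` — IVIM microvascular (pseudo-)diffusivity, 10⁻² mm²/s;
* `f_int` — IVIM intermediate (interstitial/perivascular fluid) volume
  fraction, %.

Canonical correlation analysis (CCA) finds the linear combinations of
the two sets with maximal correlation; permutation tests on Wilks
lambda decide how many canonical modes carry real association; and
redundancy analysis quantifies how much of one set's variance is
reachable through the other.

## MRI parameter estimation

### Graphical Patlak

The unidirectional two-compartment transfer model gives
$C_t(t) = v_p C_p(t) + K_i \int_0^t C_p(\tau)\,d\tau$ for tissue
concentration $C_t$ and plasma (vascular input) concentration $C_p$.
Dividing by $C_p$ linearises it: plotting $C_t/C_p$ against the "Patlak
time" $\int_0^t C_p / C_p$ makes $K_i$ the slope and $v_p$ the
intercept, estimated by ordinary least squares (`patlak_fit()`). Numerical
choices: the cumulative integral is the trapezoid rule on the sample
grid; samples with $C_p \le 10^{-12}$ are excluded (division blow-up);
the regression uses the centred form of the normal equations, which is
better conditioned when the Patlak time spans several decades; at least
3 usable points are required. The estimator is exactly unbiased on
noiseless model-generated curves because `simulate_dce_curve()` uses the
same quadrature — a deliberate pairing that makes "recovery to 10⁻⁸
relative error" a meaningful identity test rather than a quadrature
comparison. Patlak linearity assumes post-bolus quasi-equilibrium and no
backflux; `fit_window` restricts the fit to the post-bolus samples where
that holds (default: all usable samples, appropriate for the simulated
curves, which satisfy the model at all times).

### Histogram-method leakage volume

A voxel-wise $K_i$ map under pure noise is symmetric about zero, so the
negative values estimate the noise: `leakage_volume()` mirrors them
about zero and takes the `prob = 0.95` upper quantile of that symmetric
sample as the detection threshold; `VL` is the fraction of voxels above
it. Consequences worth knowing: pure-noise input yields `VL` near 0.05
(the quantile's false-positive rate) by construction, and the statistic
is invariant to positive rescaling of the map. The exact thresholding
rule of the original histogram method is not fully specified in the
literature we reconstruct it from; the mirrored-negative-noise quantile
is this package's explicit substitute, with the quantile configurable.
A map with no negative voxels is degenerate (noise cannot be
estimated): the default is an error, `no_noise = "zero"` thresholds at
zero instead.

### Three-component IVIM

The diffusion-weighted signal over the 15-value b-scheme
(0–1000 s/mm²) is modelled as
$S(b) = S_0\,[f e^{-bD^*} + f_{int} e^{-bD_{int}} +
(1 - f - f_{int}) e^{-bD_{par}}]$. `fit_ivim_3c()` minimises the
residual sum of squares by `L-BFGS-B` within a box, with the three
diffusivities on the log scale (they span two orders of magnitude). The
default boxes are non-overlapping — $D^* \in [5\times10^{-3}, 1]$,
$D_{int} \in [1.5\times10^{-3}, 5\times10^{-3}]$,
$D_{par} \in [10^{-4}, 1.5\times10^{-3}]$ mm²/s — so the compartment
ordering $D^* \ge D_{int} \ge D_{par}$ holds for every feasible point
rather than being checked after the fact; a smooth quadratic penalty
keeps $f + f_{int} < 1$. Because the objective is multi-modal in the
fractions, the optimiser is restarted from 24 Latin-hypercube points
plus the box midpoint, seeded for determinism, and the lowest-RSS
solution wins; the test suite cross-checks it against an exhaustive
grid-search oracle. A neural-network fitter could replace this stage;
the model equations — which are the scientific content — would be
unchanged, and nonlinear least squares keeps the estimator
deterministic and dependency-free. Inversion-recovery CSF suppression
is assumed already applied (signals are CSF-free), and microstructural
interpretation of $D_{par}$ is out of scope.

## Cohort preparation

Raw-score handling follows standard neuropsychology practice:
interference scores (`tmt_interference` = time B − time A;
`scwt_interference` = time 3 − mean(times 1, 2)); negation of scores
where higher means worse (both interference scores, TMT-A and the SCWT
basic-speed score), which commutes with z-scoring up to sign; *sample*
z scores with the n − 1 SD denominator (the conventional cohort choice;
canonical correlations are scale-invariant, so the denominator cannot
affect them); and domain composites as the mean z score of a domain's
tests, tolerating exactly one missing test and returning `NA` beyond
that.

**On the 13-score battery.** The test battery is counted as 13 scores
across memory (4), executive function (6) and psychomotor speed (3).
The speed domain uses a single SCWT basic-speed score — the mean time
of SCWT parts 1 and 2, the same mean that already appears inside the
SCWT interference formula — rather than the two parts separately.
Descriptive tables for such batteries sometimes list the two parts as
separate rows (which would make 14 scores); collapsing them keeps the
13-variable contract used throughout the CCA and avoids double-weighting
one test's basic-speed component.

`build_matrices()` applies, in order: the artefact-exclusion filter;
optional covariate residualization (each analysis variable replaced by
its OLS residual on an intercept plus age, sex, education — optionally
also relative brain and WMH volume); the missing-data rule; and
z-scoring. Missing data entering the 13-test CCA are handled by
listwise deletion by default — assumption-light, with the effective n
always reported — or by single mean-imputation (`missing =
"mean_impute"`) when retaining every subject matters more than the
slight variance shrinkage. Residualization before standardization makes
the canonical correlations invariant to adding any linear function of
the adjusted covariates to any variable, a property the test suite
checks end to end.

## Canonical correlation analysis

With standardized $X$ ($n \times p$) and $Y$ ($n \times q$), within-set
covariances $S_{xx}, S_{yy}$ and cross-covariance $S_{xy}$ (all with
the n − 1 denominator), the canonical correlations $r_k$ are the
singular values of $S_{xx}^{-1/2} S_{xy} S_{yy}^{-1/2}$ and the weights
are the back-transformed singular vectors. Numerical choices:

* symmetric inverse square roots via eigen-decomposition, with an
  eigenvalue floor of 10⁻¹⁰ below which the set is declared singular —
  for a near-collinear battery, `ridge` adds a diagonal regularizer
  instead of silently inverting noise;
* singular values clamped to [0, 1] (rounding can push them a few ulp
  outside);
* sign convention: per mode, both sets are flipped together so that the
  X variable with the largest |loading| loads positively — CCA is sign
  indeterminate per mode, and fixing the convention makes outputs
  reproducible across platforms (variate signs are otherwise
  data-determined);
* variates are rescaled to unit variance (the whitening already implies
  it; the rescale removes residual rounding).

Per mode $k$ the fit reports: loadings (correlation of each variable
with its set's variate), shared variance $r_k^2$, variance extracted
(mean squared loading — with $p \le q$ and full-rank $X$, the X-set
variances extracted sum to exactly 1 across modes), and the
Stewart–Love redundancy index, variance extracted × $r_k^2$. The
redundancy definition matters: with mean-squared-loadings variance
extracted, the printed identity "redundancy = variance extracted ×
shared variance" holds exactly, which is how the package's numbers
remain internally consistent at report time (`run_pipeline()` verifies
these identities before writing).

## Permutation inference

Mode significance uses Wilks $\Lambda_k = \prod_{i\ge k}(1 - r_i^2)$,
recomputed under B random permutations of the rows of $Y$ (X fixed;
permuting either set yields the same null, the convention is fixed for
reproducibility). P-values use the add-one estimator
$(1 + \#\{\Lambda^{perm} \le \Lambda^{obs}\})/(1 + B)$, which cannot be
zero at finite B. Default B = 1000. Permuting rows of one set leaves
both within-set covariances unchanged, so the implementation whitens
once and each replicate costs one small SVD — B = 1000 at n ≈ 73 runs
in milliseconds, which is what makes the calibration experiments below
cheap.

All modes are evaluated on the same replicates (simultaneous scheme),
with `step_down = TRUE` optionally enforcing monotone p-values. A known
limitation, visible in the package's own pipeline tests: when mode 1 is
strong, the simultaneous scheme is anti-conservative for later modes —
the observed $r_2$ behaves like the *first* canonical correlation of a
reduced $(p-1, q-1)$ null problem, which stochastically dominates the
second order statistic of the permuted $(p, q)$ null. In simulations
with a single planted mode, mode 1 is detected essentially always, but
an occasional later mode also crosses $\alpha = 0.05$, so "exactly one
significant mode" holds in a majority rather than near-all of
replicates. Mode-1 inference — the headline question — is unaffected:
under the global null its type-I error is nominal (the test suite
measures it at n = 73 over 200 simulated cohorts).

## What the synthetic cohorts do and do not emulate

`generate_cohort()` draws K latent standard-normal pairs $(u_k, v_k)$
with cross-pair independence, maps them to the observed sets through
loading matrices with orthonormal columns, adds homoscedastic Gaussian
noise, and rescales each column to target marginal moments (defaults:
the NVU and cognitive-score means/SDs of a typical small vessel disease
cohort, per `nvu_marginals()` / `cognition_marginals()`). Because
measurement noise attenuates correlation by
$\sqrt{(1+\sigma_x^2)(1+\sigma_y^2)}$, the generator inflates the
latent-pair correlation by exactly that factor, so the *population*
canonical correlations equal the planted `rho` exactly — the property
that makes recovery tests sharp. The default conditions are a cohort of
80 subjects with 7 artefact-flagged exclusions, planted
`rho = (0.73, 0, 0, 0, 0)`, per-variable noise SD 0.5 (in latent
units; chosen so a planted 0.73 is comfortably attainable and marginal
noise is substantial), sporadic missingness at rate 0.005 confined to
cognitive scores (a handful of cells per cohort, mimicking occasionally
skipped tests), and covariates drawn independently of the latents
(so covariate adjustment should, and in tests does, leave mode 1
essentially unchanged).

Features of real data deliberately *not* emulated: non-Gaussian
marginals (real timed scores are right-skewed; moments are matched, not
shapes); within-domain residual correlation among cognitive tests
beyond the shared latent (real batteries correlate through multiple
method factors); missingness that depends on disease severity (ours is
completely at random); covariates genuinely confounded with NVU
function (age certainly is, in vivo); and spatial structure in the MRI
maps (signals are per-voxel/per-ROI curves; no image volumes). Passing
recovery tests on these cohorts therefore validates the estimators and
the inference machinery — not the biological claim, which only patient
data can test.

Noise models for the signal simulators: additive Gaussian on tissue
concentration, and Gaussian on the IVIM magnitude signal — valid at the
high SNR the package simulates; Rician magnitude noise is available
(`rician = TRUE`) for low-SNR studies but off by default.

## Problem sizes in the test and acceptance runs

The validation experiments are sized to be decisive yet quick: moment
fidelity at n = 10⁴; planted-correlation recovery at n = 5000 (10–20
seeds, fitted $r_1$ within ±0.03 of 0.73); small-sample optimism at
n = 73 (the mean fitted $r_1$ sits ~0.07 *above* the planted 0.73 —
asserted positive, because CCA maximises sample correlation); type-I
calibration over 200 null cohorts at B = 200; power over 100 seeds at
B = 200. The permutation fast path makes all of this run in seconds.

## Known limitations

* CCA here is unregularized and unvalidated out of sample: no sparse,
  kernel or cross-validated variants. With n ≈ 70 and 18 variables the
  first sample canonical correlation is optimism-inflated by roughly
  +0.07; treat in-sample $r_1$ as an upper estimate.
* The simultaneous permutation scheme's later-mode anti-conservatism
  (above) means mode counts beyond the first significant mode should
  not be over-read.
* The histogram-method threshold rule is a reconstruction, not the
  original specification.
* The IVIM fitter assumes the three-compartment separation encoded in
  its default bounds; tissues whose diffusivities straddle a box edge
  will be projected onto it.
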