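Package: nvucca
Title: Neurovascular Unit MRI Quantification and Canonical Correlation
    Analysis of Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies neurovascular unit (NVU) function from dynamic
    contrast-enhanced and intravoxel incoherent motion MRI signal curves
    (graphical Patlak blood-brain barrier leakage rate, histogram-method
    leakage volume, three-component IVIM perfusion and intermediate-water
    fractions), prepares neuropsychological test batteries (interference
    scores, score inversion, sample-based z scores, cognitive domain
    composites, covariate residualization), and relates the two variable
    sets by canonical correlation analysis with canonical loadings,
    variance extracted, Stewart-Love redundancy indices, and sequential
    Wilks-lambda permutation tests. Includes a latent-variable cohort
    simulator with a specifiable planted canonical correlation structure
    and ground-truth MRI signal curves, so the full analysis pipeline can
    be exercised and validated end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    pracma,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
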