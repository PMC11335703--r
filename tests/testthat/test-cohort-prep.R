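# Score preprocessing: interference formulas, inversion, z scores,
# domain composites, residualization, matrix assembly.

test_that("interference scores follow their defining formulas", {
  expect_equal(tmt_interference(100, 40), 60)
  expect_equal(tmt_interference(40, 40), 0)
  expect_equal(tmt_interference(30, 40), -10)    # faster on B: valid
  expect_error(tmt_interference(0, 40), "positive")
  expect_equal(scwt_interference(150, 50, 70), 90)
  expect_equal(scwt_interference(60, 60, 60), 0)
  expect_equal(scwt_interference(76.3, 57.8, 76.3), 9.25)
  expect_error(scwt_interference(60, -1, 60), "positive")
})

test_that("score inversion negates listed columns and is an involution", {
  tab <- data.frame(tmt_a = c(1, -2, 3), other = c(4, 5, 6))
  out <- invert_scores(tab, "tmt_a")
  expect_equal(out$tmt_a, c(-1, 2, -3))
  expect_equal(out$other, tab$other)
  expect_equal(invert_scores(out, "tmt_a"), tab)
  expect_error(invert_scores(tab, "nope"), "unknown")
  # inversion commutes with z-scoring up to sign
  x <- c(3, 9, 1, 7)
  expect_equal(zscore(-x), -zscore(x))
})

test_that("z scores use observed entries, n-1 SD, and keep missingness", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(c(1, NA, 3))
  expect_true(is.na(z[2]))
  s <- sd(c(1, 3))
  expect_equal(z[c(1, 3)], c(-1, 1) / s * 1)
  expect_equal(z[1], (1 - 2) / s)
  expect_error(zscore(c(2, 2, 2)), "variance")
  expect_error(zscore(c(1, NA)), "2 observed")
})

test_that("domain composites apply the one-missing rule", {
  zt <- data.frame(
    ravlt_immediate = c(0.5, 0.5, 0.5),
    ravlt_delayed = c(-0.5, NA, NA),
    ravlt_recognition = c(1.0, 1.0, NA),
    digit_span_forward = c(0.0, 0.0, 0.0))
  comp <- domain_composite(zt, cohort_variables()$domains)
  expect_equal(comp$memory[1], 0.25)     # complete: mean of 4
  expect_equal(comp$memory[2], 0.5)      # one missing: mean of the rest
  expect_true(is.na(comp$memory[3]))     # >1 missing: undefined
  expect_error(domain_composite(data.frame(bogus = 1)), "unmapped")
})

test_that("residualization orthogonalizes against every covariate", {
  g <- toy_cohort(seed = 13)
  tab <- residualize(g$cohort, c("age", "sex", "education"))
  for (v in c(cohort_variables()$nvu, "ravlt_immediate", "tmt_a")) {
    expect_lt(abs(cor(tab[[v]], g$cohort$age)), 1e-10)
    expect_lt(abs(cor(tab[[v]], g$cohort$sex)), 1e-10)
    expect_lt(abs(mean(tab[[v]])), 1e-10)
  }
  # empty covariate list mean-centres only
  cen <- residualize(g$cohort, character(0))
  expect_equal(cen$Ki, g$cohort$Ki - mean(g$cohort$Ki), tolerance = 1e-12)
  # known-coefficient recovery: residual variance equals noise variance
  set.seed(2)
  n <- 5000
  tab2 <- g$cohort[rep(1, n), ]
  tab2$age <- rnorm(n)
  noise <- rnorm(n, 0, 0.5)
  tab2$Ki <- 2 * tab2$age + noise
  res <- residualize(tab2, "age", vars = "Ki")
  expect_lt(abs(var(res$Ki) - 0.25) / 0.25, 0.1)
  # rank-deficient design is refused
  tab3 <- g$cohort
  tab3$age2 <- tab3$age
  expect_error(residualize(tab3, c("age", "age2")), "rank")
})

test_that("build_matrices filters, standardizes and aligns the two sets", {
  g <- toy_cohort(seed = 17)   # 80 subjects, 7 flagged, no missingness
  mats <- build_matrices(invert_scores(g$cohort))
  expect_equal(mats$n_effective, 73)
  expect_equal(mats$n_excluded, 7)
  expect_equal(dim(mats$X), c(73, 5))
  expect_equal(dim(mats$Y), c(73, 13))
  expect_true(max(abs(colMeans(mats$X))) < 1e-10)
  expect_true(max(abs(colMeans(mats$Y))) < 1e-10)
  expect_equal(unname(apply(mats$X, 2, sd)), rep(1, 5))
  expect_equal(unname(apply(mats$Y, 2, sd)), rep(1, 13))
})

test_that("build_matrices missing-data rules and domain mode work", {
  g <- toy_cohort(seed = 19, missing_rate = 0.02)
  del <- build_matrices(invert_scores(g$cohort))
  expect_lt(del$n_effective, 73)
  imp <- build_matrices(invert_scores(g$cohort), missing = "mean_impute")
  expect_equal(imp$n_effective, 73)
  dom <- build_matrices(invert_scores(toy_cohort(seed = 19)$cohort),
                        mode = "domains3")
  expect_equal(ncol(dom$Y), 3)
  expect_equal(colnames(dom$Y), c("memory", "executive", "speed"))
  # too few subjects for the variable count
  small <- invert_scores(toy_cohort(seed = 23, n = 18, n_excluded = 2)$cohort)
  expect_error(build_matrices(small), "ill-posed")
})

test_that("build_matrices is idempotent on standardized complete data", {
  g <- toy_cohort(seed = 29, n_excluded = 0)
  m1 <- build_matrices(invert_scores(g$cohort))
  tab <- g$cohort
  tab[, colnames(m1$X)] <- m1$X
  # undo the inversion so the second pass re-applies it identically
  inv <- intersect(cohort_variables()$invert, colnames(m1$Y))
  Y2 <- m1$Y; Y2[, inv] <- -Y2[, inv]
  tab[, colnames(m1$Y)] <- Y2
  m2 <- build_matrices(invert_scores(tab))
  expect_equal(m2$X, m1$X, tolerance = 1e-10)
  expect_equal(m2$Y, m1$Y, tolerance = 1e-10)
})

test_that("canonical correlations are invariant to covariate adjustment of
           variables polluted by linear covariate effects", {
  g <- toy_cohort(seed = 37)
  base <- invert_scores(g$cohort)
  mats0 <- build_matrices(base, adjust = c("age", "sex", "education"))
  polluted <- base
  for (v in cohort_variables()$nvu)
    polluted[[v]] <- polluted[[v]] + 0.8 * polluted$age - 2 * polluted$sex
  for (v in cohort_variables()$cognition)
    polluted[[v]] <- polluted[[v]] - 0.3 * polluted$education
  mats1 <- build_matrices(polluted, adjust = c("age", "sex", "education"))
  expect_equal(nvu_cca(mats1)$r, nvu_cca(mats0)$r, tolerance = 1e-8)
})
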