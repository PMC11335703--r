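# CCA core: oracle equivalence, invariances, loadings, variance
# extracted, redundancy, sign convention, degenerate input.

test_that("fitted squared correlations match the eigen-solver oracle", {
  set.seed(101)
  for (i in 1:50) {
    p <- sample(2:4, 1); q <- sample(2:4, 1); n <- 200
    X <- random_matrix(n, p); Y <- random_matrix(n, q)
    fit <- nvu_cca(X, Y)
    expect_equal(fit$r^2, oracle_cca_r2(scale(X), scale(Y)),
                 tolerance = 1e-8)
  }
})

test_that("nvu_cca agrees with stats::cancor on a fixed instance", {
  set.seed(55)
  X <- random_matrix(120, 4); Y <- random_matrix(120, 6)
  fit <- nvu_cca(X, Y)
  expect_equal(fit$r, stats::cancor(scale(X), scale(Y))$cor,
               tolerance = 1e-8)
})

test_that("canonical correlations are affine invariant", {
  set.seed(7)
  X <- random_matrix(150, 5); Y <- random_matrix(150, 7)
  r0 <- nvu_cca(X, Y)$r
  A <- matrix(rnorm(25), 5, 5) + diag(5)
  B <- matrix(rnorm(49), 7, 7) + diag(7)
  shift <- function(M, v) sweep(M, 2, v, `+`)
  r1 <- nvu_cca(shift(X %*% A, rnorm(5)), shift(Y %*% B, rnorm(7)))$r
  expect_equal(r1, r0, tolerance = 1e-8)
})

test_that("variates have unit variance, orthogonality and corr(Uk,Vk)=rk", {
  set.seed(12)
  X <- random_matrix(200, 5); Y <- random_matrix(200, 8)
  fit <- nvu_cca(X, Y)
  K <- length(fit$r)
  expect_equal(unname(apply(fit$U, 2, sd)), rep(1, K), tolerance = 1e-10)
  expect_equal(unname(apply(fit$V, 2, sd)), rep(1, K), tolerance = 1e-10)
  cu <- cor(fit$U); cv <- cor(fit$V)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-8)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_equal(unname(diag(cor(fit$U, fit$V))), unname(fit$r),
               tolerance = 1e-10)
  expect_true(all(diff(fit$r) <= 1e-12))         # non-increasing
  expect_true(all(abs(fit$Lx) <= 1 + 1e-10))
  expect_true(all(abs(fit$Ly) <= 1 + 1e-10))
})

test_that("first mode maximises the correlation over random probes", {
  set.seed(3)
  X <- random_matrix(150, 5); Y <- random_matrix(150, 6)
  fit <- nvu_cca(X, Y)
  Xs <- scale(X); Ys <- scale(Y)
  best <- max(vapply(1:1000, function(i) {
    a <- rnorm(5); b <- rnorm(6)
    abs(cor(Xs %*% a, Ys %*% b))
  }, numeric(1)))
  expect_gte(fit$r[1] + 1e-10, best)
})

test_that("squared X-loadings sum to one across modes (completeness)", {
  set.seed(21)
  for (i in 1:5) {
    X <- random_matrix(120, 4); Y <- random_matrix(120, 9)
    fit <- nvu_cca(X, Y)
    expect_equal(unname(rowSums(fit$Lx^2)), rep(1, 4), tolerance = 1e-8)
    expect_equal(sum(fit$var_extracted_x), 1, tolerance = 1e-8)
  }
})

test_that("self-correlation and single-variable degeneracies are exact", {
  set.seed(9)
  X <- random_matrix(100, 4)
  fit <- nvu_cca(X, X)
  expect_equal(fit$r, rep(1, 4), tolerance = 1e-10)
  # single-variable set: loading of the variable on its variate is +-1
  y <- matrix(rnorm(100), 100, 1)
  f2 <- nvu_cca(X, y)
  expect_equal(unname(abs(f2$Ly[1, 1])), 1, tolerance = 1e-10)
})

test_that("sign convention puts the dominant X loading positive", {
  set.seed(33)
  X <- random_matrix(150, 5); Y <- random_matrix(150, 7)
  fit <- nvu_cca(X, Y)
  for (k in seq_along(fit$r))
    expect_gt(fit$Lx[which.max(abs(fit$Lx[, k])), k], 0)
  # flipping input columns cannot change the reported loadings' dominant sign
  fit2 <- nvu_cca(-X, Y)
  for (k in seq_along(fit2$r))
    expect_gt(fit2$Lx[which.max(abs(fit2$Lx[, k])), k], 0)
  expect_equal(fit2$r, fit$r, tolerance = 1e-10)
})

test_that("singular within-set covariance errors unless ridged", {
  set.seed(2)
  X <- random_matrix(60, 3)
  Xd <- cbind(X, X[, 1])                  # exactly collinear
  Y <- random_matrix(60, 4)
  expect_error(nvu_cca(Xd, Y), "singular")
  fit <- nvu_cca(Xd, Y, ridge = 1e-6)
  expect_true(all(fit$r <= 1))
  expect_error(nvu_cca(random_matrix(5, 4), random_matrix(5, 6)),
               "more observations")
})

test_that("derived summaries follow their defining identities", {
  expect_equal(shared_variance(0.73), 0.5329)
  expect_equal(round(100 * shared_variance(0.73), 1), 53.3)
  expect_equal(shared_variance(0), 0)
  expect_equal(shared_variance(1), 1)
  expect_error(shared_variance(1.2), "\\[0, 1\\]")
  expect_equal(variance_extracted(c(1, 1, 1)), 1)
  expect_equal(variance_extracted(c(0, 0)), 0)
  expect_error(variance_extracted(numeric(0)), "empty")
  expect_error(variance_extracted(c(0.2, 1.4)), "\\[-1, 1\\]")
  expect_equal(redundancy(0.240, 0.73), 0.240 * 0.5329)
  expect_equal(round(100 * redundancy(0.240, 0.73), 1), 12.8)
  expect_equal(round(100 * redundancy(0.231, 0.73), 1), 12.3)
  expect_equal(redundancy(0.5, 0), 0)
  expect_error(redundancy(1.3, 0.5), "\\[0, 1\\]")
})

test_that("canonical_loadings equal correlations and match fit loadings", {
  set.seed(14)
  X <- random_matrix(100, 5); Y <- random_matrix(100, 6)
  fit <- nvu_cca(X, Y)
  expect_equal(unname(canonical_loadings(scale(X), fit$U)),
               unname(fit$Lx), tolerance = 1e-10)
  expect_true(all(abs(canonical_loadings(scale(X), fit$U)) <= 1 + 1e-10))
  # orthonormal-column X: loadings proportional to weights
  M <- scale(matrix(rnorm(400), 100, 4), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M)) * sqrt(99)   # centred orthonormal columns, unit SD
  fq <- nvu_cca(Q, Y[, 1:4])
  expect_equal(unname(fq$Lx), unname(fq$Wx), tolerance = 1e-8)
  expect_error(canonical_loadings(matrix(1, 10, 2), matrix(rnorm(10))),
               "zero-variance")
})

test_that("methods: print, summary, coef, predict round-trip", {
  mats <- build_matrices(invert_scores(toy_cohort(seed = 41)$cohort))
  fit <- nvu_cca(mats)
  expect_output(print(fit), "Canonical correlation")
  s <- summary(fit, perm = permutation_test(fit, B = 99, seed = 1))
  expect_output(print(s), "Total redundancy")
  expect_equal(nrow(s$table), 5)
  expect_true(all(c("wilks_lambda", "p_perm") %in% names(s$table)))
  expect_equal(coef(fit, "x"), fit$Wx)
  pr <- predict(fit, newx = mats$X, newy = mats$Y)
  expect_equal(pr$U, fit$U, tolerance = 1e-10)
  expect_equal(pr$V, fit$V, tolerance = 1e-10)
})
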