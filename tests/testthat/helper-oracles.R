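# Independent oracles used to cross-check the package's own
# implementations, plus small fixture builders.

# Brute-force CCA oracle: squared canonical correlations are the
# eigenvalues of Sxx^-1 Sxy Syy^-1 Syx, computed with a generic
# eigen-solver and explicit inverses (a different numerical path from
# the whitening-SVD used by nvu_cca()).
oracle_cca_r2 <- function(X, Y) {
  Sx <- cov(X); Sy <- cov(Y); Sxy <- cov(X, Y)
  M <- solve(Sx) %*% Sxy %*% solve(Sy) %*% t(Sxy)
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  ev[seq_len(min(ncol(X), ncol(Y)))]
}

# Dense grid-search oracle for the triexponential IVIM model: exhaustive
# residual evaluation over a parameter lattice inside the default box.
oracle_ivim_grid <- function(b, S, n_grid = 8) {
  s0 <- mean(S[b == 0])
  grid <- expand.grid(
    f = seq(0, 0.2, length.out = n_grid),
    f_int = seq(0, 0.3, length.out = n_grid),
    Dstar = exp(seq(log(5e-3), log(1), length.out = n_grid)),
    D_int = seq(1.5e-3, 5e-3, length.out = n_grid),
    D_par = seq(1e-4, 1.5e-3, length.out = n_grid))
  rss <- apply(grid, 1, function(p)
    sum((S - s0 * (p[1] * exp(-b * p[3]) + p[2] * exp(-b * p[4]) +
                     (1 - p[1] - p[2]) * exp(-b * p[5])))^2))
  list(rss = min(rss), par = grid[which.min(rss), ])
}

# Random full-rank data matrix with correlated columns.
random_matrix <- function(n, p) {
  A <- matrix(rnorm(p * p), p, p)
  matrix(rnorm(n * p), n, p) %*% A
}

# Small prepared cohort used across tests (deterministic).
toy_cohort <- function(seed = 11, n = 80, rho = c(0.73, 0, 0, 0, 0),
                       missing_rate = 0, n_excluded = 7) {
  generate_cohort(latent_spec(n_subjects = n, rho = rho,
                              missing_rate = missing_rate,
                              n_excluded = n_excluded, seed = seed))
}
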