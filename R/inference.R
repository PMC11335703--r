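# Sequential significance testing of canonical modes by random
# permutation of Wilks lambda.

#' Wilks lambda for canonical mode k
#'
#' The sequential test statistic for the hypothesis that mode k and all
#' later modes carry no association:
#' `Lambda_k = prod_{i = k..K} (1 - r_i^2)`. Small values indicate
#' association in modes k..K.
#'
#' @param r Canonical correlations, in \[0, 1).
#' @param k Mode index, 1 <= k <= length(r).
#' @return Lambda_k in (0, 1\].
#' @export
#' @examples
#' wilks_lambda(c(0.73, 0.5, 0.3, 0.2, 0.1), 1)   # 0.30298
wilks_lambda <- function(r, k = 1) {
  if (any(r < 0) || any(r >= 1))
    stop("canonical correlations must lie in [0, 1)")
  if (k < 1 || k > length(r)) stop("k out of range")
  prod(1 - r[k:length(r)]^2)
}

# Lambda_k for all k at once.
wilks_lambda_all <- function(r) rev(cumprod(rev(1 - r^2)))

#' Permutation test of canonical mode significance
#'
#' For each of B replicates the rows of Y are permuted uniformly at
#' random (X fixed), the CCA refitted, and Wilks lambda recomputed for
#' every mode; the p-value of mode k is the add-one estimator
#' `(1 + #\{Lambda_k^perm <= Lambda_k^obs\}) / (1 + B)`, which can never
#' be exactly zero. All modes are evaluated on the same replicates
#' (simultaneous scheme); `step_down = TRUE` additionally enforces
#' monotone non-decreasing p-values across modes, so a later mode can
#' never look more significant than an earlier one.
#'
#' Permuting rows of one set leaves both within-set covariances
#' unchanged, so the whitening transforms are computed once and each
#' replicate reduces to the SVD of a small whitened cross-covariance;
#' B = 1000 at cohort size runs in well under a second.
#'
#' @param x n x p matrix, `"cca_matrices"` object, or `"nvu_cca"` fit
#'   (the stored standardized matrices are then reused).
#' @param y n x q matrix (ignored when `x` carries both sets).
#' @param B Number of permutations (default 1000).
#' @param seed RNG seed; recorded in the result.
#' @param step_down Enforce monotone p-values across modes.
#' @param ridge Passed to the internal whitening (see [nvu_cca()]).
#' @return Object of class `"cca_perm"`: `lambda_obs`, `p_values`,
#'   `r_obs`, `n_permutations`, `seed`, `n_effective`.
#' @export
#' @examples
#' mats <- build_matrices(invert_scores(
#'   generate_cohort(latent_spec(seed = 5))$cohort))
#' permutation_test(mats, B = 200, seed = 1)
permutation_test <- function(x, y = NULL, B = 1000, seed = 1L,
                             step_down = FALSE, ridge = 0) {
  if (inherits(x, "nvu_cca")) {
    y <- x$Y; x <- x$X
  } else if (inherits(x, "cca_matrices")) {
    y <- x$Y; x <- x$X
  }
  if (is.null(y)) stop("y is required when x is a matrix")
  if (B < 1) stop("B must be at least 1")
  X <- std_cols(x); Y <- std_cols(y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("x and y must have the same number of rows")
  K <- min(ncol(X), ncol(Y))
  # within-set covariances are invariant to row permutation of one set:
  # whiten once, then each replicate is one small SVD
  Xw <- X %*% inv_sqrt_sym(cov(X), ridge = ridge)
  Yw <- Y %*% inv_sqrt_sym(cov(Y), ridge = ridge)
  cross <- function(Ywp) {
    d <- svd(crossprod(Xw, Ywp) / (n - 1), nu = 0, nv = 0)$d
    pmin(pmax(d[seq_len(K)], 0), 1)
  }
  r_obs <- cross(Yw)
  lambda_obs <- wilks_lambda_all(r_obs)
  counts <- integer(K)
  with_seed(seed, {
    for (b in seq_len(B)) {
      lam <- wilks_lambda_all(cross(Yw[sample.int(n), , drop = FALSE]))
      counts <- counts + (lam <= lambda_obs)
    }
  })
  p <- (1 + counts) / (1 + B)
  if (step_down) p <- cummax(p)
  structure(list(lambda_obs = lambda_obs, p_values = p, r_obs = r_obs,
                 n_permutations = as.integer(B), seed = as.integer(seed),
                 n_effective = n, step_down = step_down),
            class = "cca_perm")
}

#' @export
print.cca_perm <- function(x, digits = 4, ...) {
  cat("Permutation test of canonical modes (B = ", x$n_permutations,
      ", n = ", x$n_effective, ", seed = ", x$seed, ")\n", sep = "")
  print(data.frame(mode = seq_along(x$r_obs),
                   r = round(x$r_obs, digits),
                   wilks_lambda = round(x$lambda_obs, digits),
                   p = round(x$p_values, digits)),
        row.names = FALSE)
  invisible(x)
}
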