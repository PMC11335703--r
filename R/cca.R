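# Canonical correlation analysis, written from scratch: whitening by
# symmetric inverse square roots, SVD of the whitened cross-covariance,
# loadings, variance extracted and Stewart-Love redundancy indices.

# Symmetric inverse square root of a covariance matrix via
# eigen-decomposition. Eigenvalues below `floor` indicate a (near-)
# singular set; unless a ridge is supplied this is an error.
inv_sqrt_sym <- function(S, floor = 1e-10, ridge = 0) {
  if (ridge > 0) S <- S + diag(ridge, nrow(S))
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floor)
    stop("within-set covariance is singular (min eigenvalue ",
         signif(min(e$values), 3),
         "); supply ridge > 0 to regularize")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Standardize columns (mean 0, SD 1, n-1 denominator); tolerant of
# already-standardized input.
std_cols <- function(M) {
  M <- as.matrix(M)
  s <- apply(M, 2, sd)
  if (any(s == 0)) stop("zero-variance column")
  scale(M, center = TRUE, scale = s)
}

#' Canonical correlation analysis of two variable sets
#'
#' Finds K = min(p, q) pairs of linear combinations (canonical variates)
#' U_k = X w_k and V_k = Y m_k such that corr(U_k, V_k) is maximal,
#' subject to variates within a set being mutually uncorrelated. The
#' solution is computed by whitening: with within-set covariances Sxx,
#' Syy and cross-covariance Sxy (n - 1 denominator), the singular values
#' of `Sxx^(-1/2) Sxy Syy^(-1/2)` are the canonical correlations and the
#' back-transformed singular vectors the canonical weights. Inverse
#' square roots use eigen-decompositions with an eigenvalue floor of
#' 1e-10; a near-singular set (e.g. a collinear test battery) is an
#' error unless `ridge > 0` adds a diagonal regularizer.
#'
#' For each mode the returned object carries the canonical correlation
#' r_k, the weights, the unit-variance variates, the canonical loadings
#' (correlation of each variable with its set's variate), the shared
#' variance r_k^2, the variance extracted (mean squared loading of a set
#' on its variate), and the Stewart-Love redundancy index (variance
#' extracted times shared variance) per mode and in total. Signs are
#' fixed so that, per mode, the X variable with the largest absolute
#' loading has a positive loading (both sets flipped together, so
#' corr(U_k, V_k) = +r_k always).
#'
#' Inputs are standardized internally (idempotent on already-standardized
#' matrices), so [build_matrices()] output can be passed directly via
#' `nvu_cca(mats)`.
#'
#' @param x n x p matrix (NVU set), or a `"cca_matrices"` object, in
#'   which case `y` is taken from it.
#' @param y n x q matrix (cognition set).
#' @param ridge Diagonal regularizer added to both within-set
#'   covariances; 0 (default) disables regularization.
#' @param floor Eigenvalue floor below which a within-set covariance is
#'   declared singular.
#' @return Object of class `"nvu_cca"` with components `r`, `Wx`, `Wy`,
#'   `U`, `V`, `Lx`, `Ly`, `shared_var`, `var_extracted_x/_y`,
#'   `redundancy_x_given_y`, `redundancy_y_given_x` (vectors per mode),
#'   `total_redundancy_x/_y`, `n`, and the standardized `X`, `Y`.
#' @seealso [permutation_test()] for mode significance,
#'   [summary.nvu_cca()] for the mode table.
#' @export
#' @examples
#' mats <- build_matrices(invert_scores(
#'   generate_cohort(latent_spec(seed = 11))$cohort))
#' fit <- nvu_cca(mats)
#' fit$r
nvu_cca <- function(x, y = NULL, ridge = 0, floor = 1e-10) {
  if (inherits(x, "cca_matrices")) {
    y <- x$Y
    x <- x$X
  }
  if (is.null(y)) stop("y is required when x is a matrix")
  X <- std_cols(x)
  Y <- std_cols(y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("x and y must have the same number of rows")
  p <- ncol(X); q <- ncol(Y)
  if (n <= max(p, q))
    stop("need more observations (", n, ") than variables in the ",
         "larger set (", max(p, q), ")")
  K <- min(p, q)
  Sx <- cov(X); Sy <- cov(Y); Sxy <- cov(X, Y)
  Wxh <- inv_sqrt_sym(Sx, floor, ridge)
  Wyh <- inv_sqrt_sym(Sy, floor, ridge)
  sv <- svd(Wxh %*% Sxy %*% Wyh)
  r <- pmin(pmax(sv$d[seq_len(K)], 0), 1)
  Wx <- Wxh %*% sv$u[, seq_len(K), drop = FALSE]
  Wy <- Wyh %*% sv$v[, seq_len(K), drop = FALSE]
  U <- X %*% Wx
  V <- Y %*% Wy
  # whitened weights give unit-variance variates up to numerical error
  U <- sweep(U, 2, apply(U, 2, sd), `/`)
  V <- sweep(V, 2, apply(V, 2, sd), `/`)
  Lx <- cor(X, U)
  Ly <- cor(Y, V)
  for (k in seq_len(K)) {
    j <- which.max(abs(Lx[, k]))
    if (Lx[j, k] < 0) {
      Wx[, k] <- -Wx[, k]; U[, k] <- -U[, k]; Lx[, k] <- -Lx[, k]
      Wy[, k] <- -Wy[, k]; V[, k] <- -V[, k]; Ly[, k] <- -Ly[, k]
    }
  }
  colnames(U) <- colnames(V) <- paste0("mode", seq_len(K))
  dimnames(Lx) <- list(colnames(X), paste0("mode", seq_len(K)))
  dimnames(Ly) <- list(colnames(Y), paste0("mode", seq_len(K)))
  dimnames(Wx) <- dimnames(Lx); dimnames(Wy) <- dimnames(Ly)
  ve_x <- colMeans(Lx^2)
  ve_y <- colMeans(Ly^2)
  structure(list(
    r = r, Wx = Wx, Wy = Wy, U = U, V = V, Lx = Lx, Ly = Ly,
    shared_var = r^2,
    var_extracted_x = ve_x, var_extracted_y = ve_y,
    redundancy_x_given_y = ve_x * r^2,
    redundancy_y_given_x = ve_y * r^2,
    total_redundancy_x = sum(ve_x * r^2),
    total_redundancy_y = sum(ve_y * r^2),
    n = n, X = X, Y = Y, ridge = ridge,
    call = match.call()),
    class = "nvu_cca")
}

#' Squared canonical correlation (shared variance)
#'
#' The proportion of variance shared by a pair of canonical variates is
#' the square of their canonical correlation.
#'
#' @param r Canonical correlation(s) in \[0, 1\].
#' @return r squared.
#' @export
#' @examples
#' shared_variance(0.73)   # 0.5329, i.e. 53.3%
shared_variance <- function(r) {
  if (any(r < 0) || any(r > 1)) stop("r must lie in [0, 1]")
  r^2
}

#' Variance extracted by a canonical variate
#'
#' The mean squared canonical loading of a variable set on one of its
#' variates: the proportion of the set's (standardized) variance that
#' the variate reproduces.
#'
#' @param L Vector of canonical loadings for one mode, in \[-1, 1\].
#' @return Proportion in \[0, 1\].
#' @export
variance_extracted <- function(L) {
  if (length(L) == 0) stop("empty loadings")
  if (any(abs(L) > 1 + 1e-8)) stop("loadings must lie in [-1, 1]")
  mean(L^2)
}

#' Stewart-Love redundancy index
#'
#' The proportion of variance in one variable set explainable through
#' the other set via canonical mode k: variance extracted by the set's
#' variate times the mode's shared variance. The total redundancy is the
#' sum over modes.
#'
#' @param var_extracted Variance extracted for the mode, in \[0, 1\].
#' @param r Canonical correlation of the mode, in \[0, 1\].
#' @return Redundancy proportion.
#' @export
#' @examples
#' redundancy(0.240, 0.73)   # 0.1279, i.e. 12.8%
redundancy <- function(var_extracted, r) {
  if (any(var_extracted < 0) || any(var_extracted > 1))
    stop("var_extracted must lie in [0, 1]")
  if (any(r < 0) || any(r > 1)) stop("r must lie in [0, 1]")
  var_extracted * r^2
}

#' Canonical loadings of a variable set on a set of variates
#'
#' Entry (j, k) is the Pearson correlation of variable j with variate k.
#'
#' @param M n x p (standardized) data matrix.
#' @param variates n x K matrix of canonical variates.
#' @return p x K matrix of correlations.
#' @export
canonical_loadings <- function(M, variates) {
  M <- as.matrix(M); variates <- as.matrix(variates)
  if (nrow(M) != nrow(variates)) stop("row dimensions must agree")
  if (any(apply(M, 2, sd) == 0)) stop("zero-variance column")
  cor(M, variates)
}

#' @export
print.nvu_cca <- function(x, digits = 3, ...) {
  K <- length(x$r)
  cat("Canonical correlation analysis: ", ncol(x$X), " x ", ncol(x$Y),
      " variables, n = ", x$n, ", ", K, " modes\n", sep = "")
  cat("Canonical correlations:\n")
  print(round(setNames(x$r, paste0("mode", seq_len(K))), digits))
  invisible(x)
}

#' Summary of a fitted canonical correlation analysis
#'
#' Tabulates, per mode: canonical correlation, shared variance,
#' Wilks lambda (the sequential test statistic, see [wilks_lambda()]),
#' variance extracted by each set, and both Stewart-Love redundancies.
#' If a [permutation_test()] result for the same fit is supplied, its
#' permutation p-values are appended.
#'
#' @param object An `"nvu_cca"` fit.
#' @param perm Optional `"cca_perm"` object from [permutation_test()].
#' @param ... Unused.
#' @return Object of class `"summary.nvu_cca"` with the mode table and
#'   loadings; printed as a compact report.
#' @export
summary.nvu_cca <- function(object, perm = NULL, ...) {
  K <- length(object$r)
  tab <- data.frame(
    mode = seq_len(K),
    r = object$r,
    shared_var = object$shared_var,
    wilks_lambda = vapply(seq_len(K), function(k)
      wilks_lambda(object$r, k), numeric(1)),
    var_extracted_x = object$var_extracted_x,
    var_extracted_y = object$var_extracted_y,
    redundancy_x = object$redundancy_x_given_y,
    redundancy_y = object$redundancy_y_given_x)
  if (!is.null(perm)) tab$p_perm <- perm$p_values
  structure(list(table = tab, Lx = object$Lx, Ly = object$Ly,
                 total_redundancy_x = object$total_redundancy_x,
                 total_redundancy_y = object$total_redundancy_y,
                 n = object$n),
            class = "summary.nvu_cca")
}

#' @export
print.summary.nvu_cca <- function(x, digits = 3, ...) {
  cat("Canonical modes (n = ", x$n, "):\n", sep = "")
  print(cbind(mode = x$table$mode,
              round(x$table[, -1, drop = FALSE], digits)),
        row.names = FALSE)
  cat(sprintf("Total redundancy: X given Y %.3f, Y given X %.3f\n",
              x$total_redundancy_x, x$total_redundancy_y))
  cat("\nX loadings:\n"); print(round(x$Lx, digits))
  cat("\nY loadings:\n"); print(round(x$Ly, digits))
  invisible(x)
}

#' @export
coef.nvu_cca <- function(object, set = c("x", "y", "both"), ...) {
  set <- match.arg(set)
  switch(set, x = object$Wx, y = object$Wy,
         both = list(x = object$Wx, y = object$Wy))
}

#' Project new data onto the fitted canonical variates
#'
#' New observations are standardized with their own sample moments and
#' projected through the fitted canonical weights.
#'
#' @param object An `"nvu_cca"` fit.
#' @param newx,newy Optional new data matrices with the fitted variable
#'   counts; omitted sets default to the training variates.
#' @param ... Unused.
#' @return List with matrices `U` and `V`.
#' @export
predict.nvu_cca <- function(object, newx = NULL, newy = NULL, ...) {
  U <- if (is.null(newx)) object$U else std_cols(newx) %*% object$Wx
  V <- if (is.null(newy)) object$V else std_cols(newy) %*% object$Wy
  list(U = U, V = V)
}

#' Barplot of canonical loadings for one mode
#'
#' @param x An `"nvu_cca"` fit.
#' @param mode Mode index to display.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted loadings.
#' @export
plot.nvu_cca <- function(x, mode = 1, ...) {
  old <- par(mfrow = c(1, 2), mar = c(8, 4, 3, 1))
  on.exit(par(old))
  lx <- x$Lx[, mode]; ly <- x$Ly[, mode]
  barplot(lx, las = 2, ylim = c(-1, 1), main = "NVU set",
          ylab = "canonical loading", ...)
  abline(h = 0)
  barplot(ly, las = 2, ylim = c(-1, 1), main = "Cognition set", ...)
  abline(h = 0)
  mtext(sprintf("Mode %d: r = %.2f", mode, x$r[mode]),
        outer = TRUE, line = -1.5)
  invisible(list(Lx = lx, Ly = ly))
}
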