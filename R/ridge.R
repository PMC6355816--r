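#' Ridge inverse-regression fit
#'
#' Solves the penalized least squares problem
#' \deqn{\min_\beta \sum_i (x_i - y_i^T \beta)^2 + \lambda \sum_j \beta_j^2,}
#' whose solution is \eqn{\hat\beta_\lambda = (Y^T Y + \lambda I)^{-1} Y^T x}.
#' All K+1 coefficients, including the intercept, are penalized; the design
#' already carries the ones column, and the penalty applies to every column
#' of it.  Set `penalize_intercept = FALSE` to leave the intercept
#' unpenalized (not the default behaviour of the test).
#'
#' @param design Design matrix from [build_design()] (n x (K+1), ones first).
#' @param x Numeric genotype vector of length n (the response of the inverse
#'   regression; real-valued after any residual adjustment).
#' @param lambda Single non-negative penalty.
#' @param penalize_intercept Penalize the intercept column (default `TRUE`).
#' @return List of class `"ridge_fit"` with elements `beta` (length K+1,
#'   named) and `lambda`.
#' @examples
#' y <- matrix(rnorm(30), 10, 3)
#' d <- build_design(y)
#' ridge_fit(d, rnorm(10), lambda = 2)
#' @export
ridge_fit <- function(design, x, lambda, penalize_intercept = TRUE) {
  x <- as_genotype_vector(x, nrow(design))
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("'lambda' must be a single non-negative number")
  p <- ncol(design)
  pen <- diag(p)
  if (!penalize_intercept) pen[1L, 1L] <- 0
  a <- crossprod(design) + lambda * pen
  b <- crossprod(design, x)
  beta <- tryCatch(drop(solve(a, b)), error = function(e)
    stop("singular ridge system: Y'Y + lambda*I is not invertible (rank-deficient design at lambda = ",
         lambda, ")", call. = FALSE))
  names(beta) <- colnames(design)
  structure(list(beta = beta, lambda = lambda), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("Ridge inverse-regression fit (lambda = %g)\n", x$lambda))
  print(x$beta, ...)
  invisible(x)
}

#' Leave-one-out prediction error by explicit refitting
#'
#' The reference implementation of the test statistic
#' \deqn{T_\lambda = \sum_{i=1}^n (x_i - \hat x_{-i}^\lambda)^2,}
#' where \eqn{\hat x_{-i}^\lambda} is the ridge prediction for individual i
#' from a model fit with that individual excluded.  For each penalty on the
#' grid the ridge regression is refit n times.  This is O(n) solves per
#' penalty and exists as the brute-force oracle for [loocv_errors_fast()];
#' use the fast path for anything beyond toy sizes.
#'
#' @param design Design matrix from [build_design()].
#' @param x Genotype vector of length n.
#' @param grid Penalty grid ([lambda_grid()] object or non-negative numeric
#'   vector).
#' @return Numeric vector of length M (one prediction error per penalty),
#'   named by penalty value.
#' @seealso [loocv_errors_fast()] for the closed-form path.
#' @export
loocv_errors_naive <- function(design, x, grid = lambda_grid()) {
  x <- as_genotype_vector(x, nrow(design))
  lam <- as_lambda_vector(grid)
  n <- nrow(design)
  tvals <- vapply(lam, function(l) {
    err2 <- vapply(seq_len(n), function(i) {
      fit <- ridge_fit(design[-i, , drop = FALSE], x[-i], l)
      (x[i] - sum(design[i, ] * fit$beta))^2
    }, numeric(1))
    sum(err2)
  }, numeric(1))
  names(tvals) <- signif(lam, 6)
  tvals
}
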