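#' Shared SVD factorization of the phenotype design
#'
#' Factorizes the design as \eqn{Y = U D V^T} (thin SVD, K+1 components)
#' and precomputes, for every penalty \eqn{\lambda_m} on the grid, the
#' spectral shrinkage factors \eqn{c_{\lambda,j} = d_j^2 / (d_j^2 + \lambda)}
#' and the ridge leverages \eqn{h_i^\lambda = y_i^T (Y^T Y + \lambda I)^{-1} y_i}.
#' These quantities depend only on the phenotypes and the grid, so a single
#' cache serves every permutation and, in a genome scan with complete
#' genotypes, every variant.
#'
#' @param design Design matrix from [build_design()]; requires n >= K+1.
#' @param grid Penalty grid ([lambda_grid()] or non-negative numeric vector).
#' @return List of class `"svd_cache"` with elements `U` (n x (K+1),
#'   orthonormal columns), `d` (singular values), `V`, `C` ((K+1) x M
#'   shrinkage matrix), `H` (n x M leverage matrix), `lambda`, `n`, `K`.
#' @examples
#' y <- matrix(rnorm(100), 20, 5)
#' cache <- svd_cache(build_design(y))
#' str(cache$C)
#' @export
svd_cache <- function(design, grid = lambda_grid()) {
  lam <- as_lambda_vector(grid)
  n <- nrow(design)
  p <- ncol(design)
  if (n < p)
    stop(sprintf(paste0(
      "n = %d individuals with K+1 = %d design columns: the factorization ",
      "requires n >= K+1. Reduce the number of phenotypes or enlarge the sample."),
      n, p))
  s <- svd(design, nu = p, nv = p)
  d2 <- s$d^2
  ## C[j, m] = d_j^2 / (d_j^2 + lambda_m); columns ordered as the grid
  C <- outer(d2, lam, function(a, b) a / (a + b))
  ## h_lambda = diag(U C_lambda U^T) = rowSums over j of U[,j]^2 c_{lambda,j}
  H <- (s$u * s$u) %*% C
  dimnames(C) <- list(NULL, signif(lam, 6))
  dimnames(H) <- list(rownames(design), signif(lam, 6))
  structure(list(U = s$u, d = s$d, V = s$v, C = C, H = H,
                 lambda = lam, n = n, K = p - 1L),
            class = "svd_cache")
}

#' @export
print.svd_cache <- function(x, ...) {
  cat(sprintf("SVD cache: n = %d, K = %d, %d penalties (lambda %s)\n",
              x$n, x$K, length(x$lambda),
              paste(signif(range(x$lambda), 3), collapse = " .. ")))
  invisible(x)
}

#' Leave-one-out prediction error via the closed form
#'
#' Computes \eqn{T_\lambda} for every penalty without refitting, using the
#' LOOCV identity \eqn{x_i - \hat x_{-i}^\lambda = (x_i - \hat x_i^\lambda)/(1 - h_i^\lambda)}.
#' With the cached factorization the work per genotype vector is one
#' projection \eqn{x^{(K)} = U^T x}, the shrunken fits
#' \eqn{\hat x_\lambda = U (c_\lambda * x^{(K)})}, and column sums of the
#' squared scaled residuals \eqn{Q = (x - \hat x_\lambda) / (1 - h_\lambda)}.
#' `x` may be a matrix with one genotype configuration per column (the
#' observed vector plus permutations), in which case all columns share the
#' same linear algebra.
#'
#' @param cache Cache from [svd_cache()].
#' @param x Genotype vector of length n, or an n x (B+1) matrix of genotype
#'   columns.
#' @param eps_guard Leverages must satisfy `h < 1 - eps_guard`; a violation
#'   (degenerate leave-one-out system, e.g. lambda = 0 with a row of Y
#'   outside the span of the others) is an error, not a clamp.
#' @return For a vector `x`, a named numeric vector of length M; for a
#'   matrix, a `ncol(x)` x M matrix with one row of prediction errors per
#'   genotype column.
#' @examples
#' y <- matrix(rnorm(100), 20, 5)
#' cache <- svd_cache(build_design(y))
#' loocv_errors_fast(cache, rbinom(20, 2, 0.3))
#' @export
loocv_errors_fast <- function(cache, x, eps_guard = 1e-10) {
  stopifnot(inherits(cache, "svd_cache"))
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(as.numeric(x), ncol = 1L) else as.matrix(x)
  if (anyNA(X)) stop("genotype values contain NA")
  if (nrow(X) != cache$n)
    stop(sprintf("genotype rows (%d) do not match cache n (%d)", nrow(X), cache$n))
  bad <- which(cache$H >= 1 - eps_guard, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(paste0("leverage h = %.12g for individual %d at lambda = %g ",
                        "reaches 1: leave-one-out residual undefined"),
         cache$H[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
         cache$lambda[bad[1L, 2L]]))
  XK <- crossprod(cache$U, X)                  # (K+1) x ncol(X)
  M <- length(cache$lambda)
  T <- matrix(NA_real_, ncol(X), M,
              dimnames = list(colnames(X), signif(cache$lambda, 6)))
  for (m in seq_len(M)) {
    xhat <- cache$U %*% (cache$C[, m] * XK)    # fitted values, all columns
    q <- (X - xhat) / (1 - cache$H[, m])
    T[, m] <- colSums(q * q)
  }
  if (vec_in) T[1L, ] else T
}
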