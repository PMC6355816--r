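#' Shuffle a genotype vector
#'
#' Draws a uniformly random permutation of the genotype entries using the
#' current RNG state, preserving the multiset of values.  Under the null of
#' no association the phenotype rows are exchangeable with respect to the
#' genotype, so shuffling the genotype alone generates the reference
#' distribution of the test statistic.
#'
#' @param x Genotype vector.
#' @return A permuted copy of `x`.
#' @export
permute_genotype <- function(x) {
  x[sample.int(length(x))]
}

#' Per-penalty permutation p-values
#'
#' Given the (B+1) x M matrix of prediction errors (row 1 the observed
#' data, rows 2..B+1 the permutations), computes for every row b and
#' penalty m
#' \deqn{p_{\lambda_m}^{(b)} = \#\{d \in 1..B : T_{\lambda_m}^{(d)} < T_{\lambda_m}^{(b)}\} / B.}
#' Low prediction error means association, so *smaller* permuted values
#' count against a row.  The reference set is always the B permuted rows —
#' for a permuted row this includes its own statistic, which by strict
#' inequality contributes nothing.  Ties count as "not less", so tied
#' statistics inflate p conservatively.  Implemented by a per-column sort
#' and rank lookup, exactly equivalent to the literal double loop.
#'
#' @param T_matrix Numeric (B+1) x M matrix of prediction errors.
#' @return Numeric (B+1) x M matrix of p-values in `[0, 1]`.
#' @export
per_lambda_pvalues <- function(T_matrix) {
  T_matrix <- as.matrix(T_matrix)
  B <- nrow(T_matrix) - 1L
  if (B < 1L) stop("at least one permutation row is required")
  out <- T_matrix
  for (m in seq_len(ncol(T_matrix))) {
    perm_sorted <- sort(T_matrix[-1L, m])
    out[, m] <- findInterval(T_matrix[, m], perm_sorted, left.open = TRUE) / B
  }
  out
}

#' Min-p statistic across the penalty grid
#'
#' Row-wise minimum of the per-penalty p-value matrix: the test statistic
#' is the smallest p-value attained over the ridge penalty grid, for the
#' observed data (row 1) and every permutation.
#'
#' @param p_lambda Numeric (B+1) x M matrix from [per_lambda_pvalues()].
#' @return Numeric vector of length B+1.
#' @export
minp_statistic <- function(p_lambda) {
  p_lambda <- as.matrix(p_lambda)
  if (ncol(p_lambda) < 1L) stop("at least one penalty column is required")
  apply(p_lambda, 1L, min)
}

#' Overall permutation p-value of the min-p statistic
#'
#' The single-layer procedure assesses the observed min-p statistic against
#' the permuted min-p values drawn from the same permutation set:
#' \deqn{p = \#\{b \in 1..B : T^{(b)} < T^{(0)}\} / B.}
#' With strict inequality a p-value of exactly 0 is possible; it is
#' reported downstream as "< 1/B" (see [format_pvalue()]).  Set
#' `smooth = TRUE` for the (1 + count)/(1 + B) estimator, which is never
#' zero; this is not the default.
#'
#' @param minp Numeric vector of length B+1 from [minp_statistic()]
#'   (element 1 observed).
#' @param smooth Use the add-one smoothed estimator (default `FALSE`).
#' @return A single p-value in `[0, 1]`.
#' @export
overall_pvalue <- function(minp, smooth = FALSE) {
  B <- length(minp) - 1L
  if (B < 1L) stop("at least one permutation is required")
  cnt <- sum(minp[-1L] < minp[1L])
  if (smooth) (1 + cnt) / (1 + B) else cnt / B
}

#' Format a permutation p-value at its resolution
#'
#' A permutation p-value of exactly zero only says the observed statistic
#' beat all B permutations, so it is printed as `"<1/B"`, e.g. `"<0.001"`
#' at B = 1000 or `"<1e-08"` at B = 1e8.
#'
#' @param p P-value(s).
#' @param B Number of permutations used to compute `p`.
#' @return Character vector.
#' @examples
#' format_pvalue(c(0, 0.042), B = 1000)
#' @export
format_pvalue <- function(p, B) {
  ifelse(p == 0, paste0("<", format(1 / B, scientific = 1 / B < 1e-4)),
         format(p))
}

#' Multiple-phenotype association test by cross-validation prediction error
#'
#' Tests the association between one genetic variant and K correlated
#' phenotypes.  The genotype is regressed on the phenotypes by ridge
#' regression; for every penalty on a grid the leave-one-out
#' cross-validation prediction error serves as the test statistic, each
#' penalty's statistic is converted to a permutation p-value, and the
#' minimum p-value over the grid is the overall statistic, whose own
#' significance is assessed against the same single layer of permutations.
#' The SVD of the phenotype design is computed once and reused for every
#' permutation; all permuted genotype columns go through one set of matrix
#' products.
#'
#' @param phenotypes Numeric n x K matrix of phenotypes (adjust for
#'   covariates/stratification first if needed; see
#'   [residualize_phenotypes()], [residualize_for_stratification()]).
#' @param x Genotype vector of length n (0/1/2 minor-allele counts, or
#'   real-valued residuals).  Must not be constant.
#' @param grid Penalty grid, default [lambda_grid()].
#' @param B Number of permutations (default 1000; the p-value resolution is
#'   1/B).
#' @param seed Optional integer seed for the permutation stream; if `NULL`
#'   the current RNG state is used.
#' @param smooth Use the never-zero (1+count)/(1+B) p-value estimator
#'   (default `FALSE`, matching the strict-count definition).
#' @param eps_guard Leverage guard passed to [loocv_errors_fast()].
#' @return Object of class `"multppe_test"`: a list with `p_value`,
#'   `p_display` (resolution-aware string), `minp` (length B+1, element 1
#'   observed), `p_lambda` ((B+1) x M), `T_matrix` ((B+1) x M prediction
#'   errors), `lambda`, `B`, `seed`, `n`, `K`.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(200 * 4), 200, 4)
#' g <- rbinom(200, 2, 0.3)
#' fit <- multp_pe_test(y, g, B = 200, seed = 7)
#' fit
#' @export
multp_pe_test <- function(phenotypes, x, grid = lambda_grid(), B = 1000,
                          seed = NULL, smooth = FALSE, eps_guard = 1e-10) {
  y <- as_phenotype_matrix(phenotypes)
  x <- as_genotype_vector(x, nrow(y))
  if (max(x) == min(x))
    stop("monomorphic variant: genotype vector is constant")
  if (B < 1L) stop("'B' must be at least 1")
  design <- build_design(y)
  cache <- svd_cache(design, grid)
  perm_test_core(cache, x, B = B, seed = seed, smooth = smooth,
                 eps_guard = eps_guard)
}

## Permutation test given a prebuilt SVD cache; the workhorse behind
## multp_pe_test() and the per-SNP loop of gwas_scan().  All B permuted
## genotype columns are stacked next to the observed vector so the cache's
## projections run as single matrix products.
perm_test_core <- function(cache, x, B, seed = NULL, smooth = FALSE,
                           eps_guard = 1e-10) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(x, nrow = length(x), ncol = B + 1L)
  for (b in seq_len(B)) X[, b + 1L] <- x[sample.int(length(x))]
  T_matrix <- loocv_errors_fast(cache, X, eps_guard = eps_guard)
  p_lambda <- per_lambda_pvalues(T_matrix)
  minp <- minp_statistic(p_lambda)
  p <- overall_pvalue(minp, smooth = smooth)
  structure(list(p_value = p, p_display = format_pvalue(p, B),
                 minp = minp, p_lambda = p_lambda, T_matrix = T_matrix,
                 lambda = cache$lambda, B = as.integer(B), seed = seed,
                 n = cache$n, K = cache$K),
            class = "multppe_test")
}

#' @export
print.multppe_test <- function(x, ...) {
  cat("Multiple-phenotype prediction-error association test\n")
  cat(sprintf("  n = %d individuals, K = %d phenotypes, %d penalties, B = %d permutations\n",
              x$n, x$K, length(x$lambda), x$B))
  cat(sprintf("  observed min-p statistic = %s\n", format(x$minp[1L])))
  cat(sprintf("  permutation p-value      = %s\n", x$p_display))
  invisible(x)
}

## Deterministic per-unit RNG stream: two multiplicative congruential steps
## (Park-Miller modulus) mixing a root seed with a unit index.  Keeps every
## derived seed in [1, 2^31 - 2] so set.seed() accepts it, and makes
## per-replicate / per-SNP results independent of execution order.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + as.numeric(index)) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}
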