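#' Residualize phenotypes on covariates
#'
#' Regresses each phenotype on an intercept plus the covariates by ordinary
#' least squares and returns the residuals, which replace the phenotypes in
#' the association test.  Covariate effects on the phenotypes are thereby
#' removed before the inverse regression sees them.
#'
#' @param phenotypes Numeric n x K matrix.
#' @param covariates Numeric n x G matrix of covariates, or `NULL` /
#'   zero-column matrix for intercept-only adjustment (centering).
#' @return Numeric n x K matrix of residuals, same dimnames as the input;
#'   each column is orthogonal to the intercept and every covariate.
#' @examples
#' y <- matrix(rnorm(40), 20, 2)
#' z <- matrix(rnorm(20), 20, 1)
#' r <- residualize_phenotypes(y, z)
#' crossprod(r, cbind(1, z))   # ~ 0
#' @export
residualize_phenotypes <- function(phenotypes, covariates = NULL) {
  y <- as_phenotype_matrix(phenotypes)
  q <- covariate_qr(covariates, nrow(y))
  r <- qr.resid(q, y)
  dimnames(r) <- dimnames(y)
  r
}

#' Residualize genotype and phenotypes on ancestry principal components
#'
#' Population stratification confounds the association test when allele
#' frequencies and phenotype means both differ across ancestral
#' subpopulations.  Projecting *both* the genotype and every phenotype off
#' the top ancestry PCs (plus an intercept) removes the shared structure:
#' the genotype becomes real-valued residuals, no longer 0/1/2 counts.
#'
#' @param phenotypes Numeric n x K matrix.
#' @param x Genotype vector of length n.
#' @param pcs Numeric n x L matrix of principal-component scores (e.g. from
#'   [compute_pcs()]); `NULL` or zero columns means centering only.
#' @return List with `phenotypes` (n x K residual matrix) and `x`
#'   (residual genotype vector).  A genotype fully explained by the PCs
#'   comes back (numerically) constant and the downstream test will refuse
#'   it as degenerate.
#' @export
residualize_for_stratification <- function(phenotypes, x, pcs = NULL) {
  y <- as_phenotype_matrix(phenotypes)
  x <- as_genotype_vector(x, nrow(y))
  q <- covariate_qr(pcs, nrow(y))
  ry <- qr.resid(q, y)
  dimnames(ry) <- dimnames(y)
  list(phenotypes = ry, x = drop(qr.resid(q, matrix(x))))
}

covariate_qr <- function(z, n) {
  if (is.null(z) || NCOL(z) == 0L) {
    zm <- matrix(1, n, 1L)
  } else {
    zm <- as.matrix(z)
    if (anyNA(zm)) stop("covariates contain missing values; drop individuals listwise first")
    if (nrow(zm) != n)
      stop(sprintf("covariate rows (%d) do not match phenotype rows (%d)", nrow(zm), n))
    zm <- cbind(1, zm)
  }
  q <- qr(zm)
  if (q$rank < ncol(zm))
    stop("rank-deficient covariate design (a covariate is constant or collinear)")
  q
}

#' Ancestry principal components from a genotype matrix
#'
#' Standard ancestry-PC computation: monomorphic SNP columns are dropped,
#' the remaining columns are centered and scaled to unit variance, and the
#' top L left singular vectors (scaled by their singular values) are
#' returned as PC scores.
#'
#' @param genotypes Numeric n x S genotype matrix (individuals x SNPs,
#'   additive coding).  Missing values are not allowed here; apply listwise
#'   deletion first.
#' @param L Number of components (default 10).  `L = 0` returns an n x 0
#'   matrix, making any downstream adjustment centering-only.
#' @return Numeric n x L matrix of PC scores with columns `PC1..PCL`.
#' @examples
#' g <- matrix(rbinom(50 * 20, 2, 0.3), 50, 20)
#' head(compute_pcs(g, L = 2))
#' @export
compute_pcs <- function(genotypes, L = 10) {
  g <- as.matrix(genotypes)
  if (anyNA(g)) stop("genotype matrix contains missing values; drop individuals listwise first")
  n <- nrow(g)
  if (L == 0L) return(matrix(numeric(0), n, 0L))
  sds <- apply(g, 2L, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) < L)
    stop(sprintf("L = %d components requested but only %d polymorphic SNPs available",
                 L, length(keep)))
  gs <- scale(g[, keep, drop = FALSE])
  s <- svd(gs, nu = L, nv = 0L)
  if (L > sum(s$d > max(dim(gs)) * .Machine$double.eps * s$d[1L]))
    stop("L exceeds the rank of the standardized genotype matrix")
  scores <- s$u %*% diag(s$d[seq_len(L)], L, L)
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(L)))
  scores
}
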