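#' Build the inverse-regression design matrix
#'
#' Prepends an intercept column of ones to a phenotype matrix, giving the
#' n x (K+1) design used by the ridge inverse regression of genotype on
#' phenotypes.
#'
#' @param phenotypes Numeric matrix (or data frame) with n rows
#'   (individuals) and K >= 1 columns (phenotypes).  Missing values are not
#'   allowed; handle missingness upstream (see [gwas_scan()]).
#' @return Numeric matrix of dimension n x (K+1) whose first column is
#'   identically 1, with column names `c("(Intercept)", colnames(phenotypes))`.
#' @examples
#' y <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("p1", "p2")))
#' head(build_design(y))
#' @export
build_design <- function(phenotypes) {
  y <- as_phenotype_matrix(phenotypes)
  n <- nrow(y)
  cn <- colnames(y)
  if (is.null(cn)) cn <- paste0("y", seq_len(ncol(y)))
  out <- cbind(1, y)
  colnames(out) <- c("(Intercept)", cn)
  rownames(out) <- rownames(y)
  out
}

#' Ridge penalty grid
#'
#' The penalty grid over which the min-p statistic is taken.  The default
#' places eight penalties at log(lambda) = 0, 1, 2, 3, 3.5, 3.8, 4, 4.5
#' (natural logarithm, so lambda runs from 1 to about 90), the grid used
#' throughout the simulation studies.
#'
#' @param log_lambda Strictly increasing numeric vector of log-penalties.
#' @return Numeric vector of penalties `exp(log_lambda)` with attribute
#'   `log_lambda`, of class `"lambda_grid"`.
#' @examples
#' lambda_grid()
#' lambda_grid(log_lambda = c(-2, 0, 2))
#' @export
lambda_grid <- function(log_lambda = c(0, 1, 2, 3, 3.5, 3.8, 4, 4.5)) {
  if (length(log_lambda) < 1L || anyNA(log_lambda))
    stop("'log_lambda' must be a non-empty numeric vector without NA")
  if (is.unsorted(log_lambda, strictly = TRUE))
    stop("'log_lambda' must be strictly increasing")
  structure(exp(log_lambda), log_lambda = as.numeric(log_lambda),
            class = "lambda_grid")
}

## Coerce a lambda specification (lambda_grid object or bare non-negative
## numeric vector of penalties) to a plain numeric vector.
as_lambda_vector <- function(grid) {
  lam <- as.numeric(unclass(grid))
  if (length(lam) < 1L || anyNA(lam) || any(lam < 0))
    stop("penalty grid must contain non-negative, non-missing values")
  lam
}

as_phenotype_matrix <- function(phenotypes) {
  y <- as.matrix(phenotypes)
  if (!is.numeric(y)) stop("phenotypes must be numeric")
  if (ncol(y) < 1L) stop("at least one phenotype column is required")
  if (nrow(y) < 2L) stop("at least two individuals are required")
  if (anyNA(y)) stop("phenotypes contain missing values; remove or impute upstream")
  y
}

as_genotype_vector <- function(x, n = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("genotype vector contains missing values")
  if (!is.null(n) && length(x) != n)
    stop(sprintf("genotype length (%d) does not match phenotype rows (%d)",
                 length(x), n))
  x
}
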