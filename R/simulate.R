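#' Simulation model specification
#'
#' Defines one scenario of the latent-factor phenotype model
#' \deqn{y = \varphi x + c \gamma \omega + \sqrt{1 - c^2}\, \varepsilon,}
#' where x is an additive genotype score, \eqn{\omega} is an R-vector of
#' latent factors with unit variances and pairwise correlation \eqn{\rho},
#' \eqn{\gamma} assigns each phenotype to exactly one factor, and
#' \eqn{\varepsilon} is independent standard normal noise.  Under the null
#' (\eqn{\beta = 0}) two phenotypes sharing a factor have correlation
#' \eqn{c^2} and phenotypes on different factors have correlation
#' \eqn{\rho c^2}.
#'
#' Four scenarios are supported:
#' \describe{
#'   \item{Model 1}{one factor; effects \eqn{\varphi = \beta (1, 2, \dots, K)}.}
#'   \item{Model 2}{two factors; the variant affects the second factor's
#'     phenotypes only, \eqn{\varphi = (0, \dots, 0, \beta, \dots, \beta)}.}
#'   \item{Model 3}{five factors; groups 1-3 null, group 4 constant
#'     \eqn{-\beta}, group 5 increasing \eqn{2\beta/(k+1) \cdot (1, \dots, k)}
#'     with k = K/5.}
#'   \item{Model 4}{five factors; group 1 null, group 2 constant
#'     \eqn{\beta}, group 3 constant \eqn{-\beta}, group 4 decreasing
#'     \eqn{-2\beta/(k+1) \cdot (1, \dots, k)}, group 5 increasing
#'     \eqn{2\beta/(k+1) \cdot (1, \dots, k)}.}
#' }
#'
#' @param model Model id, 1-4.
#' @param n Sample size.
#' @param K Number of phenotypes; must be divisible by the model's factor
#'   count (2 for model 2, 5 for models 3-4).
#' @param beta Effect size (0 for type-I-error studies).
#' @param maf Minor allele frequency of the simulated variant (default 0.3).
#' @param c2 Within-factor phenotype correlation \eqn{c^2} (default 0.25).
#' @param rho_c2 Between-factor phenotype correlation \eqn{\rho c^2}
#'   (default 0.14, so \eqn{\rho = 0.56} at the default \eqn{c^2}).
#' @return Object of class `"sim_model"`.
#' @examples
#' sim_model(2, n = 500, K = 10, beta = 0)
#' @export
sim_model <- function(model, n, K, beta = 0, maf = 0.3, c2 = 0.25,
                      rho_c2 = 0.14) {
  if (!model %in% 1:4) stop("'model' must be 1, 2, 3 or 4")
  R <- c(1L, 2L, 5L, 5L)[model]
  if (K %% R != 0L)
    stop(sprintf("K = %d is not divisible by the factor count R = %d of model %d",
                 K, R, model))
  if (c2 < 0 || c2 >= 1) stop("'c2' must be in [0, 1)")
  if (maf <= 0 || maf > 0.5) stop("'maf' must be in (0, 0.5]")
  rho <- if (c2 > 0) rho_c2 / c2 else 0
  if (rho < 0 || rho > 1)
    stop(sprintf("between-factor correlation rho_c2 = %g implies rho = %g outside [0, 1]",
                 rho_c2, rho))
  structure(list(model = as.integer(model), n = as.integer(n),
                 K = as.integer(K), R = R, beta = beta, maf = maf,
                 c = sqrt(c2), c2 = c2, rho = rho, rho_c2 = rho_c2),
            class = "sim_model")
}

#' @export
print.sim_model <- function(x, ...) {
  cat(sprintf(paste0("Latent-factor simulation model %d: n = %d, K = %d, R = %d,\n",
                     "  beta = %g, MAF = %g, within-factor corr = %g, between-factor corr = %g\n"),
              x$model, x$n, x$K, x$R, x$beta, x$maf, x$c2, x$rho_c2))
  invisible(x)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Independent draws with genotype probabilities \eqn{(1-p)^2},
#' \eqn{2p(1-p)}, \eqn{p^2} for scores 0, 1, 2 at minor allele frequency p.
#'
#' @param n Number of individuals.
#' @param maf Minor allele frequency in (0, 0.5].
#' @return Integer-valued genotype vector of length n.
#' @examples
#' table(simulate_genotypes(1000, 0.3))
#' @export
simulate_genotypes <- function(n, maf = 0.3) {
  if (maf <= 0 || maf > 0.5) stop("'maf' must be in (0, 0.5]")
  sample(0:2, n, replace = TRUE,
         prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
}

#' Per-phenotype genetic effects for a simulation model
#'
#' @param spec A [sim_model()] specification.
#' @return Numeric vector \eqn{\varphi} of length K.
#' @examples
#' effect_vector(sim_model(1, n = 100, K = 4, beta = 0.1))
#' @export
effect_vector <- function(spec) {
  stopifnot(inherits(spec, "sim_model"))
  K <- spec$K; beta <- spec$beta
  switch(spec$model,
    beta * seq_len(K),
    c(rep(0, K / 2), rep(beta, K / 2)),
    { k <- K / 5L
      c(rep(0, 3 * k), rep(-beta, k), 2 * beta / (k + 1) * seq_len(k)) },
    { k <- K / 5L
      c(rep(0, k), rep(beta, k), rep(-beta, k),
        -2 * beta / (k + 1) * seq_len(k), 2 * beta / (k + 1) * seq_len(k)) })
}

#' Factor-loading matrix for a simulation model
#'
#' Block-diagonal ones: each of the K phenotypes loads with weight 1 on
#' exactly one of the R factors, in contiguous blocks of size K/R.
#'
#' @param spec A [sim_model()] specification.
#' @return Numeric K x R matrix.
#' @examples
#' loading_matrix(sim_model(2, n = 100, K = 4))
#' @export
loading_matrix <- function(spec) {
  stopifnot(inherits(spec, "sim_model"))
  kronecker(diag(spec$R), matrix(1, spec$K / spec$R, 1L))
}

#' Simulate phenotypes from the latent-factor model
#'
#' Draws, per individual, the factor vector \eqn{\omega \sim MVN(0, \Sigma)}
#' with \eqn{\Sigma = \rho A + (1-\rho) I} (A the all-ones matrix) and
#' independent noise \eqn{\varepsilon_k \sim N(0,1)}, then returns
#' \eqn{y = \varphi x + c \gamma \omega + \sqrt{1-c^2}\,\varepsilon}.
#'
#' @param spec A [sim_model()] specification.
#' @param x Genotype vector of length `spec$n` (e.g. from
#'   [simulate_genotypes()]).
#' @return Numeric n x K phenotype matrix with columns `y1..yK`.
#' @examples
#' sp <- sim_model(2, n = 200, K = 10, beta = 0)
#' y <- simulate_phenotypes(sp, simulate_genotypes(200, sp$maf))
#' @export
simulate_phenotypes <- function(spec, x) {
  stopifnot(inherits(spec, "sim_model"))
  x <- as_genotype_vector(x, spec$n)
  n <- spec$n; K <- spec$K; R <- spec$R
  sigma <- spec$rho * matrix(1, R, R) + (1 - spec$rho) * diag(R)
  cs <- tryCatch(chol(sigma), error = function(e)
    stop("factor covariance is not positive definite (rho too close to 1)",
         call. = FALSE))
  omega <- matrix(stats::rnorm(n * R), n, R) %*% cs
  eps <- matrix(stats::rnorm(n * K), n, K)
  y <- outer(x, effect_vector(spec)) +
    spec$c * omega %*% t(loading_matrix(spec)) +
    sqrt(1 - spec$c2) * eps
  colnames(y) <- paste0("y", seq_len(K))
  y
}

#' Type-I-error study
#'
#' Repeatedly generates null datasets (fresh genotypes and phenotypes with
#' `beta = 0`), runs the permutation test on each, and tallies rejections
#' at each nominal level.  Replicate r uses the deterministic seed stream
#' `(seed, r)`, so a study is reproducible and chunkable.  Rejection is
#' `p <= alpha` (the permutation p-value sits on the lattice `{0, 1/B, ..., 1}`;
#' see the package vignette).
#'
#' @param spec A [sim_model()] with `beta = 0`.
#' @param replicates Number of simulated datasets (default 1000).
#' @param B Permutations per dataset (default 1000).
#' @param grid Penalty grid.
#' @param levels Nominal significance levels (default `c(0.01, 0.05)`).
#' @param seed Root seed.
#' @return Data frame with one row per level: `level`, `replicates`,
#'   `rejections`, `rate`, and the exact (Clopper-Pearson) binomial 95% CI
#'   `ci_lower`, `ci_upper`.
#' @seealso [power_study()]
#' @export
type1_study <- function(spec, replicates = 1000, B = 1000,
                        grid = lambda_grid(), levels = c(0.01, 0.05),
                        seed = 1) {
  stopifnot(inherits(spec, "sim_model"))
  if (spec$beta != 0)
    stop("type-I-error study requires a null model (beta = 0)")
  p <- replicate_pvalues(spec, replicates, B, grid, seed)
  out <- do.call(rbind, lapply(levels, function(a) {
    rej <- sum(p <= a)
    ci <- stats::binom.test(rej, replicates)$conf.int
    data.frame(level = a, replicates = replicates, rejections = rej,
               rate = rej / replicates, ci_lower = ci[1], ci_upper = ci[2])
  }))
  rownames(out) <- NULL
  out
}

#' Power study
#'
#' Rejection rate at one significance level under an alternative
#' (`beta > 0`); at `beta = 0` this is the type-I error rate.  Sweep
#' `beta`, `c2` or `rho_c2` by calling this over a vector of [sim_model()]
#' specifications.
#'
#' @inheritParams type1_study
#' @param spec A [sim_model()] specification.
#' @param level Significance level (default 0.05).
#' @return One-row data frame: `model`, `n`, `K`, `beta`, `level`,
#'   `replicates`, `rejections`, `rate`, `ci_lower`, `ci_upper`.
#' @export
power_study <- function(spec, replicates = 1000, B = 1000,
                        grid = lambda_grid(), level = 0.05, seed = 1) {
  stopifnot(inherits(spec, "sim_model"))
  p <- replicate_pvalues(spec, replicates, B, grid, seed)
  rej <- sum(p <= level)
  ci <- stats::binom.test(rej, replicates)$conf.int
  data.frame(model = spec$model, n = spec$n, K = spec$K, beta = spec$beta,
             level = level, replicates = replicates, rejections = rej,
             rate = rej / replicates, ci_lower = ci[1], ci_upper = ci[2])
}

replicate_pvalues <- function(spec, replicates, B, grid, seed) {
  vapply(seq_len(replicates), function(r) {
    set.seed(derive_seed(seed, r))
    x <- simulate_genotypes(spec$n, spec$maf)
    while (max(x) == min(x)) x <- simulate_genotypes(spec$n, spec$maf)
    y <- simulate_phenotypes(spec, x)
    multp_pe_test(y, x, grid = grid, B = B)$p_value
  }, numeric(1))
}
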