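# multppe

Joint association testing of one genetic variant against K correlated
quantitative phenotypes, using the leave-one-out cross-validation
prediction error of a ridge *inverse* regression as the test statistic.

## Why and for whom

GWAS cohorts usually measure several correlated phenotypes per disorder,
and a variant's effect on any single one is weak. Testing phenotypes
one at a time loses power to multiple-testing penalties and ignores the
correlation structure; classical joint tests (O'Brien-type combinations,
MANOVA, proportional-odds inversions, Simes-style p-value combinations)
each dominate only in particular effect configurations. This package
implements a test built to hold up *across* configurations: regress the
genotype on all phenotypes at once,

    x_i = b0 + b1 y_i1 + ... + bK y_iK + e_i,     H0: b1 = ... = bK = 0,

fit by ridge regression, `beta_hat = (Y'Y + lambda I)^{-1} Y'x`, and
score the fit by its leave-one-out prediction error

    T_lambda = sum_i ( x_i - xhat_{-i}^lambda )^2 .

Small `T_lambda` means the phenotypes predict the genotype, i.e.
association. Since no single penalty wins everywhere, `T_lambda` is
evaluated on a grid (default `log lambda = 0, 1, 2, 3, 3.5, 3.8, 4, 4.5`),
each converted to a permutation p-value, and the **minimum p over the
grid** is the statistic; a single layer of genotype permutations
calibrates it. An SVD factorization of the phenotype design is shared
across all permutations — and across all SNPs of a scan — which makes
genome-wide use practical, together with a two-stage screen (cheap
permutations everywhere, large budgets only on promising SNPs).

Intended users: statistical geneticists and biostatisticians running
multi-phenotype association scans or methods simulations.

## Worked example

```r
library(multppe)
set.seed(1)
spec <- sim_model(2, n = 500, K = 10, beta = 0.15)  # two latent factors,
x <- simulate_genotypes(spec$n, spec$maf)           # effect on one of them
y <- simulate_phenotypes(spec, x)
fit <- multp_pe_test(y, x, B = 1000, seed = 2)
fit
#> Multiple-phenotype prediction-error association test
#>   n = 500 individuals, K = 10 phenotypes, 8 penalties, B = 1000 permutations
#>   observed min-p statistic = 0.004
#>   permutation p-value      = 0.004
```

The min-p statistic 0.004 is the best per-penalty permutation p-value
the observed data achieved over the 8-point grid; the overall p-value
0.004 says 4 of 1000 genotype shuffles did better. A p-value of exactly
0 prints as `<0.001` — below the 1/B resolution.

A small scan with a spiked variant:

```r
set.seed(3)
g <- matrix(rbinom(300 * 8, 2, 0.3), 300, 8,
            dimnames = list(paste0("I", 1:300), paste0("rs", 1:8)))
y <- matrix(rnorm(300 * 5), 300, 5, dimnames = list(paste0("I", 1:300), NULL))
y[, 2] <- y[, 2] + 0.8 * g[, 3]
scan <- gwas_scan(g, y, stage1_B = 1000, stage2_B = 100000, seed = 7)
#   snp_id n_used   maf stage1_p selected stage2_p
# 1    rs1    300 0.283    0.743    FALSE       NA
# 3    rs3    300 0.300    0.000     TRUE        0   <- written as "<1e-05"
# 4    rs4    300 0.285    0.914    FALSE       NA
# ...
write_scan_results(scan, "scan.tsv")
```

Only `rs3` passes the stage-1 screen (p <= 0.005 at B = 1000) and is
re-tested at stage-2 resolution; its zero p-value serializes as
`<1e-05`. Covariates (`residualize_phenotypes()`), ancestry PCs
(`compute_pcs()`, `residualize_for_stratification()`) and PLINK
`.raw`/TSV ingestion (`read_genotypes()`) slot in around the same core.
A thin CLI wrapping these functions ships in `inst/cli/multppe.R`
(`multppe.R {test|scan|simulate} --help`).

Simulation studies: `type1_study()` and `power_study()` generate
genotypes under Hardy–Weinberg equilibrium and phenotypes from a
latent-factor model (four effect patterns, within-factor correlation
`c2`, between-factor `rho_c2`), run the test per replicate and report
rejection rates with exact binomial CIs. See the methods vignette
(`vignettes/multppe-methods.Rmd`) for the model, numerical guards and
design decisions.

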