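---
title: "Prediction-error association testing for multiple phenotypes: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction-error association testing for multiple phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multppe)
```

## The testing problem

In a GWAS of a complex disease one usually measures several correlated
quantitative phenotypes — lung-function indices, imaging scores, exercise
measures — and each variant's effect on any single one of them is weak.
Testing phenotypes one at a time costs power twice, through the
multiple-testing correction and through the discarded correlation
structure. `multppe` tests one variant against all $K$ phenotypes in a
single model by *inverting* the regression: the genotype score
$x_i \in \{0, 1, 2\}$ (minor-allele count) is the response and the
phenotypes are the predictors,

$$x_i = \beta_0 + \beta_1 y_{i1} + \dots + \beta_K y_{iK} + \varepsilon_i,$$

with null hypothesis $\beta_1 = \dots = \beta_K = 0$. One phenotype enters
per coefficient, so a single test covers the whole phenotype vector
regardless of how many phenotypes the variant actually touches or in which
directions.

GWAS phenotypes are often nearly collinear, so the ordinary
least-squares fit can be ill-posed. The model is therefore fit by ridge
regression with design $Y = (y_1, \dots, y_n)^T$, $y_i = (1, y_{i1},
\dots, y_{iK})^T$:

$$\hat\beta_\lambda = (Y^T Y + \lambda I)^{-1} Y^T x .$$

Note the intercept column sits inside $Y$ and is penalized along with
everything else — this is exactly the printed closed form that the
fast algorithm below factorizes, and it is what `ridge_fit()` implements
(an unpenalized-intercept variant exists behind
`penalize_intercept = FALSE`, off by default).

## The statistic: leave-one-out prediction error

How well the phenotypes *predict* the genotype is measured out-of-sample:

$$T_\lambda = \sum_{i=1}^n \left( x_i - \hat x^\lambda_{-i} \right)^2,$$

where $\hat x^\lambda_{-i}$ is the ridge prediction of $x_i$ from a fit
that excluded individual $i$. Small $T_\lambda$ means the phenotypes
carry information about the genotype, i.e. association. No single
$\lambda$ is best across scenarios, so the statistic is taken over a grid
$\lambda_1 < \dots < \lambda_M$ and summarized as the *min-p*:
each $T_{\lambda_m}$ is converted to a permutation p-value
$p_{\lambda_m}$ and

$$T_{\mathrm{min}p} = \min_m p_{\lambda_m}.$$

The default grid (`lambda_grid()`) has $M = 8$ points at
$\log \lambda = 0, 1, 2, 3, 3.5, 3.8, 4, 4.5$. We read the unqualified
"log" as the natural logarithm, so $\lambda$ spans roughly $1$ to $90$;
the grid is an ordinary argument everywhere, so any other spacing (or a
base-10 reading) is one call away.

## Single-layer permutation

Naively, calibrating a minimum of p-values needs a second, nested layer
of permutations. Instead the same $B$ genotype shuffles serve twice
(the microarray-style single-layer scheme): with $T^{(b)}_{\lambda_m}$
the statistic of shuffle $b$ ($b = 0$ the observed data),

$$p^{(b)}_{\lambda_m} = \frac{\#\{d \in 1..B : T^{(d)}_{\lambda_m} < T^{(b)}_{\lambda_m}\}}{B},
\qquad
p = \frac{\#\{b \in 1..B : T^{(b)}_{\mathrm{min}p} < T^{(0)}_{\mathrm{min}p}\}}{B}.$$

Three deliberate readings of these formulas, each pinned by a test
against a literal double-loop enumeration:

* the comparison is **strict**, and ties count as "not less" — tied
  statistics can only make p-values larger (conservative);
* the reference set is always $d = 1..B$, so a permuted row's own
  statistic is in its reference set (contributing nothing, by
  strictness);
* a p-value of exactly 0 is possible and only means "below the
  resolution"; it is reported as `<1/B` (`format_pvalue()`), and an
  optional `(1 + \mathrm{count})/(1 + B)` estimator is available via
  `smooth = TRUE` for users who need a strictly positive valid p.

In simulation studies we *reject* at level $\alpha$ when $p \le \alpha$
(the usual convention; the p-value lives on the lattice
$\{0, 1/B, \dots, 1\}$, so at $B = 1000$ and $\alpha = 0.05$ the two
conventions differ only in whether the lattice point $0.05$ itself
rejects).

## The fast path

$T_\lambda$ never needs $n$ refits. With the thin SVD $Y = UDV^T$
($U$ is $n \times (K{+}1)$) define the shrinkage factors
$c_{\lambda,j} = d_j^2 / (d_j^2 + \lambda)$ and leverages
$h^\lambda = \mathrm{diag}(U C_\lambda U^T)$. Then

$$x_i - \hat x^\lambda_{-i} = \frac{x_i - \hat x^\lambda_i}{1 - h^\lambda_i},
\qquad
(T_{\lambda_1}, \dots, T_{\lambda_M}) = \mathrm{colSum}(Q * Q),
\quad Q = \frac{(x - \hat x_{\lambda_1}, \dots, x - \hat x_{\lambda_M})}{1 - H},$$

with $*$ and $/$ element-wise, $\hat x_\lambda = U(c_\lambda * U^T x)$.
Everything except $x$ — $U$, $C$, $H$ — depends only on the phenotypes
and the grid, so `svd_cache()` computes it once and

* every **permutation** reuses it: `multp_pe_test()` stacks the observed
  genotype and all $B$ shuffles as columns of one $n \times (B{+}1)$
  matrix, so the per-variant cost is a handful of BLAS-3 products
  (memory $\sim n B$ doubles; at $n = 5000$, $B = 10^6$ run stage 2 in
  chunks or accept ~40 GB — the two-stage design exists precisely so
  that very large $B$ touches few SNPs);
* every **SNP** in a scan reuses it too, as long as that SNP has no
  missing calls. Per-SNP missingness changes the subsample, so
  `gwas_scan()` rebuilds the factorization for exactly those SNPs
  (an instrumented counter, `attr(res, "n_svd")`, lets tests verify the
  economy) rather than imputing.

Numerical guards: leverages must satisfy $h < 1 - 10^{-10}$; a violation
(e.g. $\lambda = 0$ with $n = K+1$, where $h \equiv 1$) is a hard error
naming the offending row, never a silent clamp. $n \ge K+1$ is required
outright — behaviour below that is not defined by the method, and we
prefer an instructive error to a guess. The vectorized multi-column path
and a per-column loop agree to BLAS rounding (relative $10^{-13}$;
matrix-matrix and matrix-vector kernels may round differently, which is
why the equivalence test uses a $10^{-12}$ tolerance rather than bit
equality), and both agree with explicit leave-one-out refitting to
$10^{-8}$ relative error.

Phenotypes are *not* standardized before the ridge fit by default —
nothing in the method's definition rescales them, and silently changing
the penalty's geometry seemed worse than documenting the sensitivity.
`scale()` the matrix first if phenotypes live on wildly different scales.

## Covariates and population stratification

Covariates $z_{i1}, \dots, z_{iG}$ are removed by regressing each
phenotype on them (with intercept) and keeping the residuals
(`residualize_phenotypes()`); the test is then invariant to adding any
linear combination of covariates to any phenotype. Population structure
needs more: both the genotype *and* the phenotypes are residualized on
the top $L$ ancestry PCs (`residualize_for_stratification()`), after
which the genotype is real-valued. `compute_pcs()` follows standard
ancestry-PC practice — center and scale each SNP column to unit variance,
drop monomorphic columns, take the top left singular vectors. $L = 10$
by default, configurable; the choice of scaling is ours (the PC
literature varies), and since $\lambda$ is searched over a grid, the
test is insensitive to it. When both covariates and PCs are supplied,
covariates are applied first. Individuals with missing phenotype,
covariate or PC entries are dropped listwise; a missing genotype drops
that individual for that SNP only.

## Genome scans and two-stage screening

Permutation p-values at genome-wide resolution ($5 \times 10^{-8}$)
would need $B \sim 10^8$ everywhere. `gwas_scan()` instead screens all
SNPs at `stage1_B = 1000` and takes only those with stage-1
$p \le 0.005$ into a second, high-resolution stage with fresh
permutation draws (whether a real analysis would extend or redraw is
unspecified; fresh draws keep the stages independently valid). The
stage-2 default ships at $B = 10^6$ — large enough to order candidate
loci, small enough for a desk run; raise it to $10^8$ for genome-wide
claims. Each SNP's permutation stream is seeded from the root seed and a
hash of the SNP *identifier*, so p-values do not depend on column order
or chunking.

## The simulation frame

`sim_model()` defines the latent-factor generator

$$y = \varphi x + c\, \gamma\, \omega + \sqrt{1 - c^2}\, \varepsilon,
\qquad \omega \sim MVN(0,\ \rho A + (1 - \rho) I),$$

with $\gamma$ a block-diagonal ones matrix assigning each phenotype to
one of $R$ factors and $\varepsilon_k \sim N(0,1)$ i.i.d. Under the null
each phenotype is standard normal, phenotypes sharing a factor correlate
at $c^2$ and phenotypes on different factors at $\rho c^2$. Four effect
patterns cover the interesting regimes — graded effects on one factor
(model 1, $R{=}1$, $\varphi = \beta(1..K)$), effects confined to one of
two factors (model 2), sparse opposite-signed effects (model 3,
$R{=}5$), and dense mixed-signed effects (model 4). Genotypes are drawn
under Hardy–Weinberg equilibrium at a given MAF.

Defaults reproduce the type-I-error study conditions: MAF $0.3$,
within-factor correlation $c^2 = 0.25$, between-factor correlation
$\rho c^2 = 0.14$ (so $\rho = 0.56$). The power figures in the source
literature quote a between-factor correlation of $0.15$ instead; both
are one argument (`rho_c2`) away, and we default to the type-I value
since that is the setting our calibration checks recompute.
`type1_study()` / `power_study()` seed replicate $r$ from
`(seed, r)`, so studies are resumable and chunkable; CIs are exact
Clopper–Pearson (the CI formula behind the published interval bounds is
not reproducible exactly, so we compute our own).

What the generator deliberately does *not* emulate: linkage
disequilibrium between SNPs, non-normal or heavy-tailed phenotypes,
relatedness, and genotype-dependent missingness. Calibration results
under this generator therefore speak to the method's null behaviour
under exchangeability, not to robustness against those features.

## Problem sizes used in the shipped checks

The package's own test suite runs scaled-down versions of the studies:
1,000 replicates at $B = 1000$ for the $n = 500$, $K = 10$ type-I cell
(the full published study used 10,000 replicates; at 1,000 the exact
binomial 95% CI must cover the nominal level), 200 replicates per point
for the four power sweeps at $n = 1000$, $K = 20$, $B = 300$, a
200,000-individual draw for the correlation-structure check, and a
two-subpopulation confounding study (allele-frequency gap 0.4, one-SD
phenotype shift, 150 background SNPs) for the PC adjustment. The
per-model effect grids in the power sweep were chosen from a coarse
pilot so that each sweep spans low to saturated power — model 1
saturates at tiny $\beta$ because $\varphi$ grows linearly up to
$K\beta$.

## A worked example

```{r example}
set.seed(1)
spec <- sim_model(2, n = 500, K = 10, beta = 0.15)
x <- simulate_genotypes(spec$n, spec$maf)
y <- simulate_phenotypes(spec, x)
fit <- multp_pe_test(y, x, B = 1000, seed = 2)
fit
```

The observed min-p statistic (here $0.004$) is the smallest
per-$\lambda$ p-value over the grid; the reported p-value is the
fraction of permutations whose min-p beat it. At a stronger effect the
report becomes `<0.001`, i.e. below the $1/B$ resolution.

## Known limitations

* The p-value resolution is $1/B$; genome-wide significance claims need
  stage-2 budgets of $10^8$ permutations.
* $n < K + 1$ is rejected rather than handled (no published definition
  of the statistic exists there).
* The permutation null assumes exchangeable individuals; residual
  relatedness or unmodelled structure beyond what the PCs capture will
  inflate the test like any other unadjusted association method.
* Binary or ordinal phenotypes are not special-cased; they enter the
  ridge fit as numeric columns.
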