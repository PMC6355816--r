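Package: multppe
Title: Joint Association Testing of Multiple Phenotypes by
    Cross-Validation Prediction Error
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests the association between a single genetic variant and
    a set of correlated quantitative phenotypes using the leave-one-out
    cross-validation prediction error of a ridge inverse regression
    (genotype regressed on phenotypes) as the test statistic.
    Significance is assessed by a single-layer min-p permutation
    procedure over a grid of ridge penalties, accelerated by a
    singular-value-decomposition factorization of the phenotype design
    that is shared across all permutations and variants.  Includes
    covariate residualization, principal-component adjustment for
    population stratification, a two-stage permutation screen for
    genome-wide scans, and a latent-factor simulation framework for
    type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
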