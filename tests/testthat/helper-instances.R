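# Small random problem instances and text fixtures, built fresh per run.

random_instance <- function(n, K, seed) {
  set.seed(seed)
  y <- matrix(rnorm(n * K), n, K)
  x <- rbinom(n, 2, 0.3)
  while (max(x) == min(x)) x <- rbinom(n, 2, 0.3)
  list(y = y, x = as.numeric(x), design = build_design(y))
}

# Literal double-loop implementation of the per-penalty p-value formula:
# p^(b)_m = #{d in 1..B : T^(d)_m < T^(b)_m} / B.  Reference for the
# sort-based implementation.
per_lambda_pvalues_bruteforce <- function(T_matrix) {
  B <- nrow(T_matrix) - 1L
  out <- T_matrix
  for (b in seq_len(nrow(T_matrix))) {
    for (m in seq_len(ncol(T_matrix))) {
      cnt <- 0L
      for (d in seq_len(B) + 1L) {
        if (T_matrix[d, m] < T_matrix[b, m]) cnt <- cnt + 1L
      }
      out[b, m] <- cnt / B
    }
  }
  out
}

# Write a PLINK .raw-dialect fixture; genotypes is a matrix of 0/1/2/NA.
write_raw_fixture <- function(genotypes, snp_names, path = tempfile(fileext = ".raw")) {
  n <- nrow(genotypes)
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE", snp_names)
  rows <- vapply(seq_len(n), function(i) {
    paste(c(paste0("F", i), paste0("I", i), "0", "0", "1", "-9",
            ifelse(is.na(genotypes[i, ]), "NA", genotypes[i, ])),
          collapse = " ")
  }, character(1))
  writeLines(c(paste(hdr, collapse = " "), rows), path)
  path
}

# Two-subpopulation dataset with a confounded null variant: allele
# frequencies and phenotype means both differ across subpopulations, while
# the variant has no effect on any phenotype within either subpopulation.
structured_null_dataset <- function(n_per_pop = 200, K = 5, n_background = 200,
                                    shift = 1, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_pop
  pop <- rep(0:1, each = n_per_pop)
  test_maf <- c(0.1, 0.5)
  x <- rbinom(n, 2, test_maf[pop + 1L])
  spec <- sim_model(1, n = n, K = K, beta = 0)
  y <- simulate_phenotypes(spec, rep(0, n)) + shift * pop
  p1 <- runif(n_background, 0.1, 0.4)
  p2 <- pmin(p1 + 0.3, 0.9)
  bg <- sapply(seq_len(n_background), function(s)
    rbinom(n, 2, ifelse(pop == 0, p1[s], p2[s])))
  list(x = x, y = y, background = bg, pop = pop)
}
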