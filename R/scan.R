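#' Two-stage genome scan over a genotype panel
#'
#' Runs the prediction-error association test for every SNP in a panel
#' against a shared set of phenotypes, with the two-stage permutation
#' screen used for genome-wide work: a cheap first pass (`stage1_B`
#' permutations) on every SNP, then a high-resolution second pass
#' (`stage2_B` permutations, fresh draws) only for SNPs whose stage-1
#' p-value is at most `stage1_threshold`.
#'
#' Phenotypes are adjusted once: covariate residualization first, then,
#' if PCs are supplied, stratification residualization of the phenotypes
#' and of each SNP.  Because the SVD factorization depends only on the
#' (adjusted) phenotypes and the penalty grid, a single [svd_cache()]
#' serves every SNP and every permutation as long as the SNP has complete
#' genotypes; a SNP with missing calls drops those individuals for that
#' SNP only, at the cost of rebuilding the factorization on the subsample.
#'
#' Each SNP's permutation stream is derived from the root seed and the SNP
#' *identifier* (not its column position), so results are reproducible
#' under any SNP ordering or chunking; stage 2 uses an independent stream.
#'
#' @param panel A [read_genotypes()] panel, or a plain numeric n x S matrix
#'   with SNP ids as column names and individual ids as rownames.
#' @param phenotypes Numeric n x K matrix (rownames = individual ids;
#'   unnamed rows are taken to align with the panel).  Individuals with any
#'   missing phenotype/covariate/PC value are dropped listwise.
#' @param covariates Optional numeric covariate matrix (same id rules).
#' @param pcs Optional matrix of ancestry PC scores (see [compute_pcs()]).
#' @param grid Penalty grid.
#' @param stage1_B Stage-1 permutations (default 1000).
#' @param stage1_threshold Stage-1 selection threshold (default 0.005).
#' @param stage2_B Stage-2 permutations (default 1e6; raise to 1e8 for
#'   genome-wide significance resolution).
#' @param seed Root seed.
#' @param flag_threshold Significance level used for the `significant`
#'   convenience flag (default the conventional genome-wide 5e-8; a flag is
#'   set only when the stage-2 resolution can support it).
#' @return Data frame of class `"multppe_scan"`, one row per SNP:
#'   `snp_id`, `n_used`, `maf`, `stage1_p`, `stage1_B`, `selected`,
#'   `stage2_p`, `stage2_B`, `significant`.  Monomorphic (or
#'   fully-confounded, post-adjustment constant) SNPs get `NA` p-values.
#'   Attribute `n_svd` counts design factorizations, for verifying cache
#'   reuse.
#' @export
gwas_scan <- function(panel, phenotypes, covariates = NULL, pcs = NULL,
                      grid = lambda_grid(), stage1_B = 1000,
                      stage1_threshold = 0.005, stage2_B = 1e6, seed = 1,
                      flag_threshold = 5e-8) {
  g <- if (inherits(panel, "genotype_panel")) panel$genotypes else as.matrix(panel)
  if (is.null(colnames(g))) colnames(g) <- paste0("snp", seq_len(ncol(g)))
  ids <- rownames(g)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(g)))

  phenotypes <- align_ids(phenotypes, ids, "phenotypes")
  covariates <- if (!is.null(covariates)) align_ids(covariates, ids, "covariates")
  pcs <- if (!is.null(pcs)) align_ids(pcs, ids, "pcs")

  ## intersect ids, then listwise deletion on phenotype/covariate/PC missingness
  present_complete <- function(m) {
    idx <- match(ids, rownames(m))
    ok <- !is.na(idx)
    ok[ok] <- stats::complete.cases(m[idx[ok], , drop = FALSE])
    ok
  }
  keep <- present_complete(phenotypes)
  if (!is.null(covariates)) keep <- keep & present_complete(covariates)
  if (!is.null(pcs)) keep <- keep & present_complete(pcs)
  if (!any(keep)) stop("no individuals shared between genotypes and phenotypes after listwise deletion")
  g <- g[keep, , drop = FALSE]
  ids <- ids[keep]
  y <- phenotypes[ids, , drop = FALSE]
  if (!is.null(covariates)) y <- residualize_phenotypes(y, covariates[ids, , drop = FALSE])
  pc_qr <- NULL
  if (!is.null(pcs) && ncol(pcs) > 0L) {
    pc_qr <- covariate_qr(pcs[ids, , drop = FALSE], length(ids))
    y <- qr.resid(pc_qr, y)
  }

  n_svd <- 0L
  full_cache <- svd_cache(build_design(y), grid)
  n_svd <- n_svd + 1L
  S <- ncol(g)
  res <- data.frame(snp_id = colnames(g), n_used = NA_integer_,
                    maf = NA_real_, stage1_p = NA_real_,
                    stage1_B = as.integer(stage1_B), selected = FALSE,
                    stage2_p = NA_real_, stage2_B = as.integer(stage2_B),
                    significant = NA, stringsAsFactors = FALSE)

  snp_pvalue <- function(s, B, stage) {
    x <- g[, s]
    obs <- !is.na(x)
    res$n_used[s] <<- sum(obs)
    if (sum(obs) < ncol(y) + 2L || max(x[obs]) == min(x[obs])) return(NA_real_)
    res$maf[s] <<- mean(x[obs]) / 2
    if (all(obs)) {
      cache <- full_cache
      xs <- x
      if (!is.null(pc_qr)) xs <- drop(qr.resid(pc_qr, matrix(x)))
    } else {
      ys <- y[obs, , drop = FALSE]
      xs <- x[obs]
      if (!is.null(pc_qr)) {
        qs <- covariate_qr(pcs[ids[obs], , drop = FALSE], sum(obs))
        ys <- qr.resid(qs, ys)
        xs <- drop(qr.resid(qs, matrix(xs)))
      }
      cache <- svd_cache(build_design(ys), grid)
      n_svd <<- n_svd + 1L
    }
    if (max(xs) == min(xs)) return(NA_real_)   # fully confounded variant
    snp_seed <- derive_seed(derive_seed(seed, id_hash(colnames(g)[s])), stage)
    perm_test_core(cache, xs, B = B, seed = snp_seed)$p_value
  }

  for (s in seq_len(S)) res$stage1_p[s] <- snp_pvalue(s, stage1_B, 1L)
  res$selected <- !is.na(res$stage1_p) & res$stage1_p <= stage1_threshold
  for (s in which(res$selected)) res$stage2_p[s] <- snp_pvalue(s, stage2_B, 2L)
  res$significant <- ifelse(res$selected & 1 / stage2_B <= flag_threshold,
                            res$stage2_p < flag_threshold, NA)
  if (all(is.na(res$stage1_p)))
    stop("all SNPs monomorphic or degenerate: no testable variant in the panel")
  attr(res, "n_svd") <- n_svd
  class(res) <- c("multppe_scan", "data.frame")
  res
}

#' @export
print.multppe_scan <- function(x, ...) {
  cat(sprintf("Genome scan: %d SNPs, %d selected for stage 2 (threshold on stage-1 p)\n",
              nrow(x), sum(x$selected)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more SNPs\n")
  invisible(x)
}

## Match a matrix to panel individual ids: rownames are authoritative when
## present, otherwise the rows are assumed aligned with the panel.
align_ids <- function(m, ids, what) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) {
    if (nrow(m) != length(ids))
      stop(sprintf("%s has %d rows but the panel has %d individuals and no ids to match by",
                   what, nrow(m), length(ids)))
    rownames(m) <- ids
  }
  m
}

## Order-independent 31-adic string hash onto [0, 2^31 - 2]; keeps per-SNP
## permutation streams tied to the SNP identity, not its column position.
id_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483629
  h
}
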