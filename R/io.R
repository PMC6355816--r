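#' Read a genotype panel
#'
#' Reads an individuals-by-SNPs matrix of additive genotype scores from
#' either a PLINK `.raw` export (`--recode A`: whitespace-separated, header
#' `FID IID PAT MAT SEX PHENOTYPE SNP1_A ...`, values 0/1/2/NA) or a plain
#' TSV (header row of SNP identifiers, first column the individual
#' identifier).  Columns whose coded-allele frequency exceeds 0.5 are
#' flipped to `2 - g` so that scores always count the minor allele; flips
#' are recorded and reported.
#'
#' @param path Path to the genotype file.
#' @param format `"plink-raw"`, `"tsv"`, or `"auto"` (default: decide from
#'   the header).
#' @return Object of class `"genotype_panel"`: list with `genotypes`
#'   (numeric n x S matrix, `NA` for missing), `snp_ids`, `individual_ids`,
#'   `flipped` (logical per SNP), `maf` (minor-allele frequency per SNP
#'   after orientation).
#' @export
read_genotypes <- function(path, format = c("auto", "plink-raw", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    hdr <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
    format <- if (length(hdr) >= 6L &&
                  identical(toupper(hdr[1:6]),
                            c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
      "plink-raw" else "tsv"
  }
  if (format == "plink-raw") {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             na.strings = c("NA", "-9"), colClasses = NA)
    if (ncol(tab) < 7L) stop("malformed PLINK .raw file: no SNP columns after the 6 header fields")
    ids <- as.character(tab[[2L]])                       # IID
    g <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             na.strings = "NA")
    if (ncol(tab) < 2L) stop("malformed genotype TSV: need an id column plus at least one SNP")
    ids <- as.character(tab[[1L]])
    g <- as.matrix(tab[, -1L, drop = FALSE])
  }
  if (anyDuplicated(ids)) stop("duplicate individual identifiers in ", path)
  storage.mode(g) <- "double"
  ok <- is.na(g) | g == 0 | g == 1 | g == 2
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("genotype value %s (individual %s, SNP %s) is not 0/1/2/NA",
                 format(g[bad[1L], bad[2L]]), ids[bad[1L]], colnames(g)[bad[2L]]))
  }
  freq <- colMeans(g, na.rm = TRUE) / 2
  flipped <- !is.na(freq) & freq > 0.5
  if (any(flipped)) {
    g[, flipped] <- 2 - g[, flipped]
    message(sum(flipped), " SNP(s) flipped to minor-allele coding: ",
            paste(utils::head(colnames(g)[flipped], 5L), collapse = ", "),
            if (sum(flipped) > 5L) ", ..." else "")
  }
  rownames(g) <- ids
  structure(list(genotypes = g, snp_ids = colnames(g), individual_ids = ids,
                 flipped = flipped, maf = colMeans(g, na.rm = TRUE) / 2),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d individuals x %d SNPs (%d flipped to minor-allele coding, %d missing calls)\n",
              length(x$individual_ids), length(x$snp_ids), sum(x$flipped),
              sum(is.na(x$genotypes))))
  invisible(x)
}

#' Read an individuals-by-variables TSV (phenotypes, covariates, PCs)
#'
#' Expects a header row of variable names and the individual identifier in
#' the first column; all remaining columns must be numeric.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with individual ids as rownames.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           na.strings = "NA")
  if (ncol(tab) < 2L) stop("malformed TSV: need an id column plus at least one variable")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate individual identifiers in ", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_phenotypes
#' @export
read_covariates <- read_phenotypes

#' Write / read genome-scan results
#'
#' Serializes a [gwas_scan()] result to TSV, one row per SNP.  P-values of
#' exactly zero are written at the resolution of the permutation count,
#' e.g. `<0.001` after 1000 permutations or `<1e-06` after 10^6; SNPs not
#' taken into stage 2 have an empty `stage2_p` cell.  `read_scan_results()`
#' restores the data frame (a `<...>` cell reads back as numeric 0).
#'
#' @param result Data frame from [gwas_scan()].
#' @param path Output path.
#' @return `write_scan_results()` returns `path` invisibly;
#'   `read_scan_results()` returns the restored data frame.
#' @export
write_scan_results <- function(result, path) {
  out <- result
  out$stage1_p <- format_pvalue_col(result$stage1_p, result$stage1_B)
  out$stage2_p <- format_pvalue_col(result$stage2_p, result$stage2_B)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  tab$stage1_p <- parse_pvalue_col(tab$stage1_p)
  tab$stage2_p <- parse_pvalue_col(tab$stage2_p)
  for (col in c("n_used", "stage1_B", "stage2_B"))
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  for (col in c("maf"))
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  for (col in c("selected", "significant"))
    if (col %in% names(tab)) tab[[col]] <- as.logical(tab[[col]])
  tab
}

format_pvalue_col <- function(p, B) {
  vapply(seq_along(p), function(i) {
    if (is.na(p[i])) "" else format_pvalue(p[i], B[i])
  }, character(1))
}

parse_pvalue_col <- function(s) {
  s <- as.character(s)
  s[is.na(s)] <- ""
  out <- rep(NA_real_, length(s))
  lt <- startsWith(s, "<")
  out[lt] <- 0
  num <- !lt & s != ""
  out[num] <- as.numeric(s[num])
  out
}
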