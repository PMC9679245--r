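#' Genotype dataset container
#'
#' A `geno_set` bundles the three aligned tables every downstream statistic
#' operates on: an individuals x SNPs dosage matrix, a per-SNP table, and a
#' per-sample table, plus optional per-cell allele depths.
#'
#' Dosages count copies of the *alternate* allele: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing. This
#' orientation is used consistently everywhere (allele frequencies `p` are
#' alternate-allele frequencies).
#'
#' @param geno integer matrix, individuals in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids); entries in `{0,1,2,NA}`.
#' @param snps data.frame with one row per SNP column: `id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, and optionally `tag_id`. Summary columns
#'   (`mac`, `maf`, `call_rate`) are (re)computed.
#' @param samples data.frame with one row per genotype row: `sample_id`,
#'   `population`. `missingness` is (re)computed.
#' @param ad optional list with matrices `ref` and `alt` of the same shape as
#'   `geno`: read depths supporting each allele.
#'
#' @return An object of class `geno_set`.
#' @export
geno_set <- function(geno, snps, samples, ad = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (nrow(snps) != ncol(geno))
    stop("snps table has ", nrow(snps), " rows but geno has ", ncol(geno), " columns")
  if (nrow(samples) != nrow(geno))
    stop("samples table has ", nrow(samples), " rows but geno has ", nrow(geno), " rows")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  if (anyDuplicated(paste(snps$chrom, snps$pos))) stop("duplicated (chrom, pos)")
  ord <- order(snps$chrom, snps$pos)
  if (!identical(ord, seq_len(nrow(snps))))
    stop("snps table must be sorted by chrom then pos")
  if (is.null(snps$id)) snps$id <- paste0(snps$chrom, ":", snps$pos)
  rownames(geno) <- samples$sample_id
  colnames(geno) <- snps$id
  if (!is.null(ad)) {
    stopifnot(identical(dim(ad$ref), dim(geno)), identical(dim(ad$alt), dim(geno)))
    storage.mode(ad$ref) <- storage.mode(ad$alt) <- "integer"
    if (any(ad$ref < 0 | ad$alt < 0, na.rm = TRUE)) stop("negative allele depths")
    dimnames(ad$ref) <- dimnames(ad$alt) <- dimnames(geno)
  }
  x <- structure(list(geno = geno, snps = snps, samples = samples, ad = ad),
                 class = "geno_set")
  refresh_stats(x)
}

#' Recompute per-SNP and per-sample summary statistics
#'
#' Updates `mac`, `maf`, `call_rate` in the SNP table and `missingness` in
#' the sample table from the current genotype matrix. Called by every filter
#' so the tables never go stale.
#'
#' @param x a `geno_set`.
#' @return the updated `geno_set`.
#' @export
refresh_stats <- function(x) {
  g <- x$geno
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  # minor allele count: min of alt and ref allele counts among called genotypes
  mac <- pmin(alt, 2L * n_called - alt)
  x$snps$mac <- as.integer(mac)
  x$snps$maf <- ifelse(n_called > 0, mac / (2 * n_called), NA_real_)
  x$snps$call_rate <- n_called / nrow(g)
  x$samples$missingness <- rowMeans(is.na(g))
  x
}

#' @export
print.geno_set <- function(x, ...) {
  cat("geno_set:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs\n")
  cat("  populations:", length(unique(x$samples$population)), "\n")
  cat("  chromosomes:", length(unique(x$snps$chrom)), "\n")
  cat("  allele depths:", if (is.null(x$ad)) "absent" else "present", "\n")
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x a `geno_set`.
#' @param ind logical/integer index over individuals (default: keep all).
#' @param snp logical/integer index over SNPs (default: keep all).
#' @return the subsetted `geno_set` with summaries recomputed.
#' @export
subset_geno <- function(x, ind = NULL, snp = NULL) {
  if (is.null(ind)) ind <- seq_len(nrow(x$geno))
  if (is.null(snp)) snp <- seq_len(ncol(x$geno))
  ad <- x$ad
  if (!is.null(ad))
    ad <- list(ref = ad$ref[ind, snp, drop = FALSE], alt = ad$alt[ind, snp, drop = FALSE])
  x$geno <- x$geno[ind, snp, drop = FALSE]
  x$snps <- x$snps[snp, , drop = FALSE]
  rownames(x$snps) <- NULL
  x$samples <- x$samples[ind, , drop = FALSE]
  rownames(x$samples) <- NULL
  x$ad <- ad
  refresh_stats(x)
}

#' Per-population alternate-allele frequencies
#'
#' @param x a `geno_set`.
#' @param snp optional SNP index.
#' @return matrix populations x SNPs of alternate-allele frequencies; `NA`
#'   where a population has no called genotype at a SNP.
#' @export
pop_allele_freqs <- function(x, snp = NULL) {
  if (!is.null(snp)) x <- subset_geno(x, snp = snp)
  pops <- sort(unique(x$samples$population))
  out <- matrix(NA_real_, length(pops), ncol(x$geno),
                dimnames = list(pops, colnames(x$geno)))
  for (p in pops) {
    g <- x$geno[x$samples$population == p, , drop = FALSE]
    n <- colSums(!is.na(g))
    out[p, ] <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  }
  out
}
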