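#' Quality-control filter cascade
#'
#' Applies the standard RADseq SNP/individual filters in a fixed, auditable
#' order: (1) drop SNPs with minor allele count below `min_mac`; (2) drop
#' SNPs with call rate below `min_snp_call`; (3) recompute individual
#' missingness on the retained SNPs and drop individuals missing more than
#' `max_ind_missing` of them. SNP-level filters always run before the
#' individual-level filter so the missingness an individual is judged on
#' refers to the retained marker set.
#'
#' @param x a [geno_set].
#' @param min_mac minimum minor allele count (default 3).
#' @param min_snp_call minimum SNP call rate in `[0,1]` (default 0.70).
#' @param max_ind_missing maximum individual missingness in `[0,1]`
#'   (default 0.50).
#' @return list with `data` (the filtered `geno_set`) and `report`, a
#'   data.frame of per-step counts removed/retained.
#' @export
filter_cascade <- function(x, min_mac = 3, min_snp_call = 0.70,
                           max_ind_missing = 0.50) {
  stopifnot(min_mac >= 0, min_snp_call >= 0, min_snp_call <= 1,
            max_ind_missing >= 0, max_ind_missing <= 1)
  report <- data.frame(step = character(), removed = integer(),
                       retained = integer(), stringsAsFactors = FALSE)
  note <- function(step, removed, retained)
    rbind(report, data.frame(step = step, removed = removed, retained = retained))

  keep_snp <- x$snps$mac >= min_mac
  report <- note("snp_min_mac", sum(!keep_snp), sum(keep_snp))
  x <- subset_geno(x, snp = keep_snp)

  keep_snp <- x$snps$call_rate >= min_snp_call
  report <- note("snp_min_call_rate", sum(!keep_snp), sum(keep_snp))
  x <- subset_geno(x, snp = keep_snp)

  if (ncol(x$geno) == 0) {
    err <- simpleError("all SNPs removed by filter cascade")
    err$report <- report
    stop(err)
  }

  keep_ind <- x$samples$missingness <= max_ind_missing
  report <- note("ind_max_missing", sum(!keep_ind), sum(keep_ind))
  x <- subset_geno(x, ind = keep_ind)

  if (nrow(x$geno) == 0) {
    err <- simpleError("all individuals removed by filter cascade")
    err$report <- report
    stop(err)
  }
  list(data = x, report = report)
}

#' Thin SNPs by physical distance
#'
#' Greedy per-chromosome scan in position order: a SNP is kept iff it lies at
#' least `min_bp` base pairs from the last kept SNP on the same chromosome
#' (the `vcftools --thin` rule).
#'
#' @param snps a SNP table (sorted by chrom, pos).
#' @param min_bp minimum spacing in bp.
#' @return integer vector of retained SNP row indices.
#' @export
thin_by_distance <- function(snps, min_bp) {
  stopifnot(min_bp > 0)
  ord <- order(snps$chrom, snps$pos)
  if (!identical(ord, seq_len(nrow(snps)))) stop("SNP table must be sorted by chrom, pos")
  keep <- logical(nrow(snps))
  last_chrom <- NA_character_
  last_pos <- -Inf
  for (i in seq_len(nrow(snps))) {
    if (!identical(snps$chrom[i], last_chrom) || snps$pos[i] - last_pos >= min_bp) {
      keep[i] <- TRUE
      last_chrom <- snps$chrom[i]
      last_pos <- snps$pos[i]
    }
  }
  which(keep)
}

#' Keep one SNP per RAD tag
#'
#' Retains the first SNP (in position order) of each `tag_id`; SNPs without a
#' tag id are all retained.
#'
#' @param snps SNP table.
#' @return integer vector of retained SNP row indices.
#' @export
one_snp_per_tag <- function(snps) {
  tag <- snps$tag_id
  if (is.null(tag)) return(seq_len(nrow(snps)))
  keep <- is.na(tag) | !duplicated(tag, incomparables = NA)
  which(keep)
}

#' Paralog statistics and filter (heterozygosity / read-ratio deviation)
#'
#' For each SNP computes H, the proportion of called genotypes that are
#' heterozygous, and D, the pooled-read binomial z-score
#' `D = (A - B) / sqrt(A + B)` where A and B are total reference and
#' alternate read counts summed over heterozygous individuals. At a true
#' single-copy locus reads in heterozygotes are split Binomial(0.5), so |D|
#' far from 0 (or excess H) indicates collapsed paralogs. SNPs with no
#' heterozygotes get D = 0 and are retained.
#'
#' @param x a [geno_set] carrying allele depths.
#' @param max_h maximum heterozygosity (default 0.55).
#' @param max_abs_d maximum |D| (default 5).
#' @return list with `keep` (retained SNP indices), `table` (per-SNP H and D)
#'   and `n_missing_ad` (het genotypes lacking depths, excluded from A,B).
#' @export
hdplot_filter <- function(x, max_h = 0.55, max_abs_d = 5) {
  if (is.null(x$ad)) stop("hdplot_filter requires allele depths (AD)")
  g <- x$geno
  het <- !is.na(g) & g == 1L
  n_called <- colSums(!is.na(g))
  H <- ifelse(n_called > 0, colSums(het) / n_called, 0)
  refm <- x$ad$ref; altm <- x$ad$alt
  usable <- het & !is.na(refm) & !is.na(altm)
  n_missing_ad <- sum(het & !usable)
  if (n_missing_ad > 0)
    warning(n_missing_ad, " heterozygous genotypes lack AD; excluded from read totals")
  A <- colSums(refm * usable, na.rm = TRUE)
  B <- colSums(altm * usable, na.rm = TRUE)
  D <- ifelse(A + B > 0, (A - B) / sqrt(A + B), 0)
  tab <- data.frame(id = x$snps$id, H = H, D = D,
                    total_reads = A + B, stringsAsFactors = FALSE)
  keep <- unname(which(H <= max_h & abs(D) <= max_abs_d))
  list(keep = keep, table = tab, n_missing_ad = n_missing_ad)
}

#' Pairwise relatedness and duplicate flagging
#'
#' Yang-type genomic relatedness between individuals j and k:
#' `A_jk = mean over SNPs of (x_j - 2p)(x_k - 2p) / (2p(1-p))`
#' with `x` the alternate-allele dosage and `p` the alternate-allele
#' frequency, restricted to SNPs with `maf >= min_maf`; SNPs missing in
#' either member of a pair are skipped for that pair. Pairs exceeding
#' `threshold` are flagged as putative duplicates.
#'
#' @param x a [geno_set].
#' @param min_maf MAF floor for the SNPs used (default 0.05).
#' @param threshold relatedness above which a pair is flagged (default 0.9).
#' @return data.frame of all pairs with `sample_1`, `sample_2`,
#'   `relatedness`, `flagged`.
#' @export
relatedness_dedup <- function(x, min_maf = 0.05, threshold = 0.9) {
  if (nrow(x$geno) < 2) stop("need at least 2 samples")
  use <- x$snps$maf >= min_maf & x$snps$maf > 0
  if (!any(use)) stop("no SNPs pass the MAF filter")
  g <- x$geno[, use, drop = FALSE]
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)
  z <- sweep(g, 2, 2 * p)                       # x - 2p, NA where missing
  w <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")  # standardized dosage
  obs <- !is.na(w)
  w0 <- w; w0[!obs] <- 0
  num <- tcrossprod(w0)              # sum over shared SNPs of products
  den <- tcrossprod(obs * 1)         # number of SNPs shared per pair
  A <- num / den
  idx <- which(upper.tri(A), arr.ind = TRUE)
  out <- data.frame(sample_1 = rownames(g)[idx[, 1]],
                    sample_2 = rownames(g)[idx[, 2]],
                    relatedness = A[idx], stringsAsFactors = FALSE)
  out$flagged <- out$relatedness > threshold
  out
}

#' Filter SNPs on RAD tags with too many haplotypes
#'
#' RAD loci assembling more than `max_haps` distinct haplotypes are likely
#' collapsed repeats; all their SNPs are removed. SNPs without a tag id (or
#' whose tag is absent from `counts`) pass.
#'
#' @param counts named integer vector or two-column data.frame
#'   (`tag_id`, `n_haplotypes`).
#' @param snps SNP table with a `tag_id` column.
#' @param max_haps maximum allowed haplotype count (default 10).
#' @return integer vector of retained SNP row indices.
#' @export
haplotype_count_filter <- function(counts, snps, max_haps = 10) {
  if (is.data.frame(counts)) {
    cnt <- counts$n_haplotypes
    names(cnt) <- counts$tag_id
  } else cnt <- counts
  if (any(cnt < 1)) stop("haplotype counts must be >= 1")
  tag <- snps$tag_id
  bad_tags <- names(cnt)[cnt > max_haps]
  keep <- is.na(tag) | !(tag %in% bad_tags)
  which(keep)
}
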