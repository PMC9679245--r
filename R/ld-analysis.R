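# SNP indices on `chrom` passing the LD eligibility filters: MAF floor and
# minimum pairwise spacing (greedy thin in position order).
ld_eligible <- function(x, chrom, min_maf = 0.01, min_bp = 400) {
  idx <- which(x$snps$chrom == chrom & x$snps$maf >= min_maf)
  if (!length(idx)) return(integer(0))
  sub <- x$snps[idx, , drop = FALSE]
  keep <- thin_by_distance(sub, min_bp = min_bp)
  idx[keep]
}

#' Pairwise r-squared within a chromosome
#'
#' `r2` is the squared Pearson correlation of alternate-allele dosages over
#' individuals called at both SNPs (the composite unphased-genotype LD
#' measure). SNPs are first restricted to `maf >= min_maf` and thinned to a
#' minimum spacing of `min_bp`; pairs separated by more than `max_bp_window`
#' are omitted. Zero-variance SNPs yield missing r2.
#'
#' @param x a [geno_set].
#' @param chrom chromosome id.
#' @param snp_ids optional explicit SNP ids (must lie on `chrom`); the
#'   MAF/spacing filters are still applied.
#' @param min_maf MAF floor (default 0.01).
#' @param min_bp minimum pairwise spacing in bp (default 400).
#' @param max_bp_window maximum separation in bp (default 30e6).
#' @return data.frame: `id_a`, `id_b`, `pos_a`, `pos_b`, `bp_apart`, `r2`.
#' @export
pairwise_r2 <- function(x, chrom, snp_ids = NULL, min_maf = 0.01,
                        min_bp = 400, max_bp_window = 30e6) {
  idx <- ld_eligible(x, chrom, min_maf = min_maf, min_bp = min_bp)
  if (!is.null(snp_ids)) idx <- idx[x$snps$id[idx] %in% snp_ids]
  if (length(idx) < 2) stop("fewer than 2 eligible SNPs")
  g <- x$geno[, idx, drop = FALSE]
  pos <- x$snps$pos[idx]
  ids <- x$snps$id[idx]
  r2m <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
  pr <- which(upper.tri(r2m), arr.ind = TRUE)
  out <- data.frame(id_a = ids[pr[, 1]], id_b = ids[pr[, 2]],
                    pos_a = pos[pr[, 1]], pos_b = pos[pr[, 2]],
                    bp_apart = abs(pos[pr[, 2]] - pos[pr[, 1]]),
                    r2 = r2m[pr], stringsAsFactors = FALSE)
  out[out$bp_apart <= max_bp_window, , drop = FALSE]
}

# Mean pairwise dosage r2 among a set of SNP columns (pairwise-complete).
mean_pairwise_r2 <- function(g) {
  r2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
  mean(r2[upper.tri(r2)], na.rm = TRUE)
}

#' Permutation test for elevated LD among target SNPs
#'
#' The statistic is the mean pairwise r2 among the target SNPs. Each of
#' `n_iter` iterations draws, without replacement, an equally sized random
#' SNP set from the same chromosome under the same MAF/spacing eligibility
#' filters, building the chromosomal null; `p = (1 + #{null >= obs}) /
#' (n_iter + 1)`.
#'
#' @param x a [geno_set].
#' @param target_ids SNP ids of the target set (>= 2, one chromosome).
#' @param chrom chromosome id.
#' @param n_iter permutation draws (default 10000).
#' @param min_maf,min_bp eligibility filters matching [pairwise_r2].
#' @param seed optional RNG seed.
#' @return list: `observed`, `p`, `null_mean`, `null_sd`, `n_iter`,
#'   `n_targets`, plus `null` (the null draws).
#' @export
ld_background_permutation <- function(x, target_ids, chrom, n_iter = 10000,
                                      min_maf = 0.01, min_bp = 400,
                                      seed = NULL) {
  tgt <- match(target_ids, x$snps$id)
  if (anyNA(tgt)) stop("unknown SNP ids")
  if (length(tgt) < 2) stop("need >= 2 target SNPs (no pairs otherwise)")
  if (any(x$snps$chrom[tgt] != chrom)) stop("targets must lie on ", chrom)
  pool <- ld_eligible(x, chrom, min_maf = min_maf, min_bp = min_bp)
  if (length(pool) < length(tgt))
    stop("chromosome has too few eligible SNPs to draw from")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean_pairwise_r2(x$geno[, tgt, drop = FALSE])
  null <- vapply(seq_len(n_iter), function(i) {
    s <- sample(pool, length(tgt))
    mean_pairwise_r2(x$geno[, s, drop = FALSE])
  }, numeric(1))
  list(observed = obs, p = (1 + sum(null >= obs)) / (n_iter + 1),
       null_mean = mean(null), null_sd = stats::sd(null),
       n_iter = n_iter, n_targets = length(tgt), null = null)
}

#' Chromosome-wide LD matrix with extended-block flagging
#'
#' Dense symmetric r2 matrix over the (optionally thinned) SNPs of one
#' chromosome, for heatmap export, plus a scan for extended LD blocks: each
#' SNP gets a local statistic (mean r2 to its `neighbor_snps` nearest
#' following SNPs); SNPs whose local mean exceeds `block_r2` are flagged,
#' flagged runs separated by fewer than `max_gap_snps` unflagged SNPs are
#' merged, and merged runs spanning more than `block_span_bp` are reported
#' as blocks (bounds = first/last flagged SNP; `mean_r2` = mean pairwise r2
#' over the block's SNPs).
#'
#' @param x a [geno_set].
#' @param chrom chromosome id.
#' @param thin_to optional cap on the number of SNPs (evenly spaced subset).
#' @param min_maf MAF floor (default 0.01).
#' @param block_r2 local mean-r2 threshold for a block (default 0.2).
#' @param block_span_bp minimum block span in bp (default 1e6).
#' @param neighbor_snps window for the local statistic (default 10).
#' @param max_gap_snps unflagged gap bridged inside a block (default 5).
#' @return list: `r2` (matrix with SNP ids), `pos`, `blocks` (data.frame
#'   `start_bp`, `end_bp`, `n_snps`, `mean_r2`).
#' @export
ld_heatmap_matrix <- function(x, chrom, thin_to = NULL, min_maf = 0.01,
                              block_r2 = 0.2, block_span_bp = 1e6,
                              neighbor_snps = 10, max_gap_snps = 5) {
  idx <- which(x$snps$chrom == chrom & x$snps$maf >= min_maf)
  if (!is.null(thin_to) && length(idx) > thin_to)
    idx <- idx[round(seq(1, length(idx), length.out = thin_to))]
  g <- x$geno[, idx, drop = FALSE]
  pos <- x$snps$pos[idx]
  r2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
  dimnames(r2) <- list(x$snps$id[idx], x$snps$id[idx])
  m <- length(idx)
  # max of the forward and backward neighborhood means, so SNPs at a block
  # edge (half their neighborhood outside the block) are still flagged while
  # background SNPs next to a block (low r2 to everything) are not
  local_mean <- vapply(seq_len(m), function(i) {
    fwd <- if (i < m) mean(r2[i, (i + 1):min(m, i + neighbor_snps)], na.rm = TRUE)
           else NA_real_
    bwd <- if (i > 1) mean(r2[i, max(1, i - neighbor_snps):(i - 1)], na.rm = TRUE)
           else NA_real_
    max(fwd, bwd, na.rm = TRUE)
  }, numeric(1))
  flagged <- !is.na(local_mean) & local_mean > block_r2
  blocks <- data.frame(start_bp = integer(), end_bp = integer(),
                       n_snps = integer(), mean_r2 = numeric())
  hits <- which(flagged)
  if (length(hits)) {
    grp <- cumsum(c(1, diff(hits) > max_gap_snps))
    for (gme in split(hits, grp)) {
      i1 <- min(gme); i2 <- max(gme)
      if (pos[i2] - pos[i1] > block_span_bp) {
        sub <- r2[i1:i2, i1:i2]
        blocks <- rbind(blocks, data.frame(
          start_bp = pos[i1], end_bp = pos[i2], n_snps = i2 - i1 + 1,
          mean_r2 = mean(sub[upper.tri(sub)], na.rm = TRUE)))
      }
    }
  }
  list(r2 = r2, pos = pos, blocks = blocks)
}
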