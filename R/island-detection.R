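#' Sliding-window outlier enrichment scan
#'
#' Windows of `window_snps` SNPs advance by `step_snps` SNPs per chromosome
#' (SNP ordinal space). Windows containing at least `min_outliers` outlier
#' SNPs are candidate windows. Chromosomes with fewer SNPs than one window
#' are skipped (recorded in the `skipped` attribute).
#'
#' @param outliers logical vector, one flag per SNP row of `snps`.
#' @param snps SNP table sorted by chrom, pos.
#' @param window_snps window size in SNPs (default 250).
#' @param step_snps step size in SNPs (default 50).
#' @param min_outliers minimum outlier count for a candidate window
#'   (default 10).
#' @return data.frame of candidate windows: `chrom`, `start_ord`, `end_ord`
#'   (within-chromosome SNP ordinals, 0-based half-open), `n_outliers`;
#'   attribute `skipped` lists chromosomes shorter than one window.
#' @export
sliding_window_scan <- function(outliers, snps, window_snps = 250,
                                step_snps = 50, min_outliers = 10) {
  stopifnot(window_snps > 0, step_snps > 0, length(outliers) == nrow(snps))
  out <- list()
  skipped <- character(0)
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    m <- length(idx)
    if (m < window_snps) {
      skipped <- c(skipped, ch)
      next
    }
    flags <- outliers[idx]
    starts <- seq(0L, m - window_snps, by = step_snps)
    cnt <- vapply(starts, function(s) sum(flags[(s + 1):(s + window_snps)]),
                  integer(1))
    hit <- cnt >= min_outliers
    if (any(hit))
      out[[ch]] <- data.frame(chrom = ch, start_ord = starts[hit],
                              end_ord = starts[hit] + window_snps,
                              n_outliers = cnt[hit], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_ord = integer(),
               end_ord = integer(), n_outliers = integer())
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Merge candidate windows into candidate regions
#'
#' Overlapping-or-adjacent candidate windows (in SNP ordinal space, same
#' chromosome) are merged; each merged run is trimmed to the positions of its
#' outermost outlier SNPs, so region size does not depend on window size.
#'
#' @param wins candidate windows from [sliding_window_scan].
#' @param outliers logical vector per SNP row of `snps`.
#' @param snps SNP table.
#' @return data.frame of regions: `chrom`, `start_bp`, `end_bp`,
#'   `n_outliers`, `outlier_ids` (list column of SNP ids).
#' @export
merge_and_trim_regions <- function(wins, outliers, snps) {
  regions <- list()
  for (ch in unique(wins$chrom)) {
    wch <- wins[wins$chrom == ch, , drop = FALSE]
    wch <- wch[order(wch$start_ord), , drop = FALSE]
    idx <- which(snps$chrom == ch)
    grp_start <- wch$start_ord[1]
    grp_end <- wch$end_ord[1]
    flush <- function(s, e) {
      ords <- (s + 1):e           # 1-based ordinals inside the chromosome
      snp_rows <- idx[ords]
      hit <- snp_rows[outliers[snp_rows]]
      if (!length(hit)) return(NULL)
      data.frame(chrom = ch, start_bp = min(snps$pos[hit]),
                 end_bp = max(snps$pos[hit]), n_outliers = length(hit),
                 outlier_ids = I(list(snps$id[hit])), stringsAsFactors = FALSE)
    }
    if (nrow(wch) > 1) for (i in 2:nrow(wch)) {
      if (wch$start_ord[i] <= grp_end) {
        grp_end <- max(grp_end, wch$end_ord[i])
      } else {
        regions <- c(regions, list(flush(grp_start, grp_end)))
        grp_start <- wch$start_ord[i]
        grp_end <- wch$end_ord[i]
      }
    }
    regions <- c(regions, list(flush(grp_start, grp_end)))
  }
  regions <- regions[!vapply(regions, is.null, logical(1))]
  if (!length(regions))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_outliers = integer()))
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Region pairwise F_ST with bootstrap confidence intervals
#'
#' Pairwise Weir-Cockerham theta restricted to the region's outlier SNPs,
#' with percentile bootstrap over loci (`n_boot` resamples). A pair is
#' significant when its 95% CI excludes zero.
#'
#' @param x a [geno_set].
#' @param snp_ids SNP ids (region outliers) to use; at least 2.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional RNG seed.
#' @return data.frame per population pair: `pop_1`, `pop_2`, `theta`,
#'   `ci_lower`, `ci_upper`, `significant`.
#' @export
region_fst_ci <- function(x, snp_ids, n_boot = 1000, conf = 0.95,
                          seed = NULL) {
  snp <- match(snp_ids, x$snps$id)
  if (anyNA(snp)) stop("unknown SNP ids")
  if (length(snp) < 2)
    stop("bootstrap over loci needs >= 2 SNPs; use wc_fst for a point estimate")
  if (!is.null(seed)) set.seed(seed)
  pops <- sort(unique(x$samples$population))
  rows <- list()
  alpha2 <- (1 - conf) / 2
  for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
    keep <- x$samples$population %in% pops[c(i, j)]
    comp <- wc_components(x$geno[keep, snp, drop = FALSE],
                          x$samples$population[keep])
    tot <- colSums(comp)
    if (all(is.na(tot)) || sum(tot, na.rm = TRUE) == 0)
      stop("region monomorphic in populations ", pops[i], "/", pops[j])
    theta <- sum(comp["a", ], na.rm = TRUE) / sum(tot, na.rm = TRUE)
    L <- length(snp)
    boots <- vapply(seq_len(n_boot), function(b) {
      s <- sample.int(L, L, replace = TRUE)
      sum(comp["a", s], na.rm = TRUE) / sum(tot[s], na.rm = TRUE)
    }, numeric(1))
    ci <- stats::quantile(boots, c(alpha2, 1 - alpha2), na.rm = TRUE,
                          names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      pop_1 = pops[i], pop_2 = pops[j], theta = theta,
      ci_lower = ci[1], ci_upper = ci[2],
      significant = ci[1] > 0 | ci[2] < 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Paired Wilcoxon test of region vs genome-wide differentiation
#'
#' One-sided (region > genome) signed-rank test over matched population
#' pairs; exact distribution for 25 or fewer pairs, otherwise the normal
#' approximation with continuity correction.
#'
#' @param region_theta,genome_theta numeric vectors of pairwise theta, same
#'   pair order.
#' @return list: `p`, `statistic`, `n_pairs`.
#' @export
region_vs_genome_test <- function(region_theta, genome_theta) {
  stopifnot(length(region_theta) == length(genome_theta))
  d <- region_theta - genome_theta
  if (all(d == 0)) {
    warning("all paired differences are zero")
    return(list(p = 1, statistic = NA_real_, n_pairs = length(d)))
  }
  wt <- stats::wilcox.test(region_theta, genome_theta, paired = TRUE,
                           alternative = "greater",
                           exact = length(d) <= 25, correct = TRUE)
  list(p = wt$p.value, statistic = unname(wt$statistic), n_pairs = length(d))
}

#' Population x SNP alternate-allele-frequency matrix for a region
#'
#' @param x a [geno_set].
#' @param snp_ids region SNP ids.
#' @return list: `af` (populations x SNPs matrix, NA where a population has
#'   no called genotypes) and `mean_af` (per-population row means).
#' @export
region_allele_frequencies <- function(x, snp_ids) {
  snp <- match(snp_ids, x$snps$id)
  if (anyNA(snp)) stop("unknown SNP ids")
  af <- pop_allele_freqs(x, snp = snp)
  list(af = af, mean_af = rowMeans(af, na.rm = TRUE))
}

#' Write candidate regions as BED
#'
#' BED intervals are 0-based half-open; bp positions here are 1-based, so
#' start = start_bp - 1, end = end_bp.
#' @param regions data.frame from [merge_and_trim_regions].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start_bp - 1L, regions$end_bp,
                    paste0("region_", seq_len(nrow(regions))),
                    regions$n_outliers)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
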