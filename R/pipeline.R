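#' Pipeline run configuration
#'
#' All analysis thresholds in one validated list. Defaults are the standard
#' values for Rapture-style datasets: MAC >= 3, SNP call rate >= 0.70,
#' individual missingness <= 0.50, relatedness flag > 0.9, 400 bp thinning,
#' scan MAF floor 0.05, outlier q < 0.01, 250-SNP windows stepped by 50 with
#' >= 10 outliers, LD filters MAF >= 0.01 / >= 400 bp, 10000 permutations,
#' 1000 bootstrap resamples, 50-SNP local-PCA windows, 40 MDS dimensions,
#' 3-SD flagging. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_mac = 3, min_snp_call = 0.70, max_ind_missing = 0.50,
    relatedness_threshold = 0.9, relatedness_min_maf = 0.05,
    thin_bp = 400, max_haplotypes = 10,
    hdplot_max_h = 0.55, hdplot_max_abs_d = 5,
    scan_min_maf = 0.05, scan_thin_r2 = 0.2, scan_window_snps = 50,
    scan_k_max = 10, scan_k_override = NULL, q_threshold = 0.01,
    window_snps = 250, step_snps = 50, min_outliers = 10,
    ld_min_maf = 0.01, ld_min_bp = 400,
    n_perm = 10000, n_boot = 1000,
    local_pca_window = 50, mds_dims = 40, sd_factor = 3,
    scopes = NULL, seed = 1,
    skip = character())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  with(cfg, stopifnot(
    min_mac >= 0, min_snp_call >= 0, min_snp_call <= 1,
    max_ind_missing >= 0, max_ind_missing <= 1,
    scan_min_maf >= 0, scan_min_maf <= 0.5, q_threshold > 0, q_threshold < 1,
    window_snps > 0, step_snps > 0, min_outliers > 0,
    n_perm >= 1, n_boot >= 1, sd_factor > 0))
  class(cfg) <- "run_config"
  cfg
}

#' Regional sample scopes
#'
#' Splits the sample table into analysis scopes: the full set plus one subset
#' per region. `scope_map` maps population code to one or more regions
#' (populations may belong to several scopes); every population must appear.
#'
#' @param samples a sample table (`sample_id`, `population`).
#' @param scope_map named list or named character vector:
#'   population -> region(s); value "excluded" drops the population from
#'   regional scopes (it stays in "full").
#' @return named list of sample_id vectors, starting with `full`.
#' @export
define_scopes <- function(samples, scope_map) {
  pops <- unique(samples$population)
  missing_pops <- setdiff(pops, names(scope_map))
  if (length(missing_pops))
    stop("scope map missing population(s): ", paste(missing_pops, collapse = ", "))
  scopes <- list(full = samples$sample_id)
  regions <- setdiff(unique(unlist(scope_map)), "excluded")
  for (r in regions) {
    in_r <- names(scope_map)[vapply(scope_map, function(v) r %in% v, logical(1))]
    ids <- samples$sample_id[samples$population %in% in_r]
    if (!length(ids)) stop("scope ", r, " is empty")
    scopes[[r]] <- ids
  }
  scopes
}

# Run one pcadapt-style scan (thin -> choose K -> scan) on a sample subset.
scan_scope <- function(x, cfg, scope_name, sample_ids = NULL) {
  if (!is.null(sample_ids))
    x <- subset_geno(x, ind = x$samples$sample_id %in% sample_ids)
  thin <- ld_clump_thin(x, thin_r2 = cfg$scan_thin_r2,
                        window_snps = cfg$scan_window_snps,
                        min_mac = cfg$min_mac)
  K <- choose_k_scree(x, thin = thin$keep, k_max = cfg$scan_k_max,
                      override = cfg$scan_k_override)$K
  pcadapt_scan(x, thin = thin$keep, K = K, min_maf = cfg$scan_min_maf,
               q_threshold = cfg$q_threshold, scope = scope_name,
               seed = cfg$seed)
}

#' Run the full analysis pipeline
#'
#' Stage order: QC filter cascade -> diversity / pairwise F_ST (and IBD when
#' spatial inputs are given) -> genome scans (full dataset plus each
#' regional scope) -> sliding-window island detection on the combined
#' outlier set -> per-region LD permutation tests -> local-PCA inversion
#' screen of region chromosomes with genotype clustering and haplotype
#' frequencies. Stages named in `cfg$skip` ("qc", "stats", "ibd", "scan",
#' "islands", "ld", "inversion") are skipped (stages depending on a skipped
#' stage degrade gracefully; the scan runs on the unfiltered data when QC is
#' skipped).
#'
#' @param x a [geno_set].
#' @param cfg a [run_config].
#' @param raster,coords optional spatial inputs for the IBD stage.
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSV/JSON/BED under it.
#' @return list with elements `qc`, `diversity`, `fst`, `ibd`, `scans`,
#'   `outliers`, `regions`, `region_stats`, `ld`, `inversion`, `manifest`.
#' @export
run_pipeline <- function(x, cfg = run_config(), raster = NULL, coords = NULL,
                         out_dir = NULL) {
  res <- list()
  t0 <- Sys.time()
  skip <- cfg$skip

  if (!("qc" %in% skip)) {
    fc <- filter_cascade(x, min_mac = cfg$min_mac,
                         min_snp_call = cfg$min_snp_call,
                         max_ind_missing = cfg$max_ind_missing)
    x <- fc$data
    res$qc <- fc$report
  }

  if (!("stats" %in% skip)) {
    res$diversity <- diversity_stats(x)
    res$fst <- pairwise_fst(x, n_perm = 0)
  }

  if (!("ibd" %in% skip) && !is.null(raster) && !is.null(coords) &&
      !is.null(res$fst)) {
    d <- least_cost_distances(raster, coords)
    pops <- sort(unique(x$samples$population))
    d <- d[pops, pops]
    res$ibd <- ibd_regression(res$fst$theta[pops, pops], d,
                              n_perm = cfg$n_perm, seed = cfg$seed)
  }

  if (!("scan" %in% skip)) {
    scans <- list(scan_scope(x, cfg, "full"))
    if (!is.null(cfg$scopes)) {
      sc <- define_scopes(x$samples, cfg$scopes)
      for (nm in setdiff(names(sc), "full"))
        scans <- c(scans, list(scan_scope(x, cfg, nm, sample_ids = sc[[nm]])))
    }
    res$scans <- scans
    res$outliers <- combine_outlier_sets(scans)
  }

  if (!("islands" %in% skip) && !is.null(res$outliers)) {
    flag <- x$snps$id %in% res$outliers$id
    wins <- sliding_window_scan(flag, x$snps, window_snps = cfg$window_snps,
                                step_snps = cfg$step_snps,
                                min_outliers = cfg$min_outliers)
    res$regions <- merge_and_trim_regions(wins, flag, x$snps)
    if (nrow(res$regions) > 0) {
      stats_list <- list()
      for (i in seq_len(nrow(res$regions))) {
        ids <- res$regions$outlier_ids[[i]]
        rc <- region_fst_ci(x, ids, n_boot = cfg$n_boot, seed = cfg$seed)
        genome_theta <- res$fst$theta[cbind(rc$pop_1, rc$pop_2)]
        wt <- region_vs_genome_test(rc$theta, genome_theta)
        af <- region_allele_frequencies(x, ids)
        stats_list[[i]] <- list(fst_ci = rc, wilcoxon = wt, af = af)
      }
      res$region_stats <- stats_list
    }
  }

  if (!("ld" %in% skip) && !is.null(res$regions) && nrow(res$regions) > 0) {
    res$ld <- lapply(seq_len(nrow(res$regions)), function(i) {
      ids <- res$regions$outlier_ids[[i]]
      ids <- ids[x$snps$maf[match(ids, x$snps$id)] >= cfg$ld_min_maf]
      if (length(ids) < 2) return(NULL)
      ld_background_permutation(x, ids, res$regions$chrom[i],
                                n_iter = cfg$n_perm,
                                min_maf = cfg$ld_min_maf,
                                min_bp = cfg$ld_min_bp, seed = cfg$seed)
    })
  }

  if (!("inversion" %in% skip) && !is.null(res$regions) && nrow(res$regions) > 0) {
    res$inversion <- lapply(seq_len(nrow(res$regions)), function(i) {
      ch <- res$regions$chrom[i]
      lp <- local_pca_mds(x, ch, window_snps = cfg$local_pca_window,
                          mds_dims = cfg$mds_dims, sd_factor = cfg$sd_factor)
      ids <- res$regions$outlier_ids[[i]]
      cl <- tryCatch(genotype_cluster_pca(x, ids, seed = cfg$seed),
                     error = function(e) NULL)
      hf <- if (!is.null(cl)) haplotype_frequency(cl) else NULL
      list(chrom = ch, local_pca = lp, clusters = cl, haplotype_freq = hf)
    })
  }

  res$manifest <- list(
    config = unclass(cfg), seed = cfg$seed,
    n_ind = nrow(x$geno), n_snp = ncol(x$geno),
    package_version = as.character(utils::packageVersion("radpopgen")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Write the main stage outputs as plain-text files under `dir`.
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$qc)) wt(res$qc, "qc_report.tsv")
  if (!is.null(res$diversity)) wt(res$diversity, "diversity.tsv")
  if (!is.null(res$fst))
    utils::write.table(res$fst$theta, file.path(dir, "fst_matrix.tsv"),
                       sep = "\t", quote = FALSE)
  if (!is.null(res$scans))
    for (s in res$scans) wt(s$table, paste0("scan_", s$scope, ".tsv"))
  if (!is.null(res$regions) && nrow(res$regions) > 0) {
    wt(res$regions[, c("chrom", "start_bp", "end_bp", "n_outliers")],
       "regions.tsv")
    write_regions_bed(res$regions, file.path(dir, "regions.bed"))
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
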