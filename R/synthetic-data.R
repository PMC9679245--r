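#' Simulation configuration
#'
#' Defaults emulate the study system the package is designed around: 17
#' demes split into two weakly diverged regional groups (9 "northwest", 8
#' "east"), ~49 individuals per deme, a low genome-wide background
#' differentiation (overall weighted F_ST around 0.006), a few localized
#' divergence islands, and one large (~8.4 Mb) non-recombining haplotype
#' block at ~9.6% frequency with no minor-haplotype homozygotes.
#'
#' @param n_pops number of demes (default 17).
#' @param n_ind individuals per deme (default 49).
#' @param n_regions demes are split as evenly as possible into this many
#'   regional groups (default 2).
#' @param n_chrom chromosomes (default 6).
#' @param snps_per_chrom SNPs per chromosome (default 2000).
#' @param chrom_length_bp chromosome length (default 60e6).
#' @param fst_deme Balding-Nichols differentiation of demes around their
#'   regional allele frequency (default 0.0035).
#' @param fst_region differentiation of regional groups around the ancestral
#'   frequency (default 0.003); 0 gives a single-level island model whose
#'   expected multi-locus theta equals `fst_deme`.
#' @param missing_rate per-genotype missing probability (default 0.05).
#' @param simulate_ad simulate read depths (default TRUE).
#' @param depth_mean,depth_size negative-binomial read-depth model
#'   (defaults 20, 5).
#' @param islands list of island specs, each a list(chrom, start_bp, end_bp,
#'   fst, affected_pops); default two islands; pass `list()` or `NULL` for
#'   none.
#' @param inversion inversion spec list(chrom, start_bp, end_bp, f,
#'   allow_minor_homozygotes, divergent_frac); default an 8.4 Mb block at
#'   f = 0.096 on the last chromosome; pass `NULL` for none.
#' @param seed RNG seed (default 1).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pops = 17, n_ind = 49, n_regions = 2, n_chrom = 6,
                       snps_per_chrom = 2000, chrom_length_bp = 60e6,
                       fst_deme = 0.0035, fst_region = 0.003,
                       missing_rate = 0.05, simulate_ad = TRUE,
                       depth_mean = 20, depth_size = 5,
                       islands, inversion, seed = 1) {
  if (missing(islands)) islands <- list(
    list(chrom = "chr02", start_bp = 20e6, end_bp = 24e6, fst = 0.15,
         affected_pops = NULL),   # NULL = first regional group
    list(chrom = "chr04", start_bp = 35e6, end_bp = 38e6, fst = 0.20,
         affected_pops = "pop01"))
  if (is.null(islands)) islands <- list()
  if (missing(inversion)) inversion <- list(
    chrom = sprintf("chr%02d", n_chrom), start_bp = 45.4e6, end_bp = 53.8e6,
    f = 0.096, allow_minor_homozygotes = FALSE, divergent_frac = 0.85)
  cfg <- list(n_pops = n_pops, n_ind = n_ind, n_regions = n_regions,
              n_chrom = n_chrom, snps_per_chrom = snps_per_chrom,
              chrom_length_bp = chrom_length_bp, fst_deme = fst_deme,
              fst_region = fst_region, missing_rate = missing_rate,
              simulate_ad = simulate_ad, depth_mean = depth_mean,
              depth_size = depth_size, islands = islands,
              inversion = inversion, seed = seed)
  stopifnot(n_pops >= 1, n_ind >= 2, missing_rate >= 0, missing_rate < 1,
            fst_deme >= 0, fst_deme < 1, fst_region >= 0, fst_region < 1)
  class(cfg) <- "sim_config"
  cfg
}

# Balding-Nichols draw: deme frequency around `p` with differentiation F.
bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  stats::rbeta(length(p), a, b)
}

#' Simulate the neutral multi-deme baseline
#'
#' Hierarchical Balding-Nichols allele-frequency model: per SNP an ancestral
#' frequency is drawn Uniform(0.05, 0.95); each regional group draws its
#' frequency around the ancestral one with differentiation `fst_region`, and
#' each deme around its regional frequency with `fst_deme`. Genotypes are
#' Hardy-Weinberg binomial draws within demes, with independent missingness
#' and (optionally) negative-binomial read depths, heterozygote reads split
#' Binomial(0.5). Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config] (islands/inversion specs are ignored here; see
#'   [inject_divergence_island], [inject_inversion], [simulate_dataset]).
#' @return object of class `sim_dataset`: `data` (a [geno_set]), `truth`
#'   (list with `ancestral_p`, `deme_p`, `region_of_pop`, empty
#'   `islands`/`inversion` slots, `seed`), `config`.
#' @export
simulate_baseline <- function(cfg) {
  set.seed(cfg$seed)
  n_snp <- cfg$n_chrom * cfg$snps_per_chrom
  chrom <- rep(sprintf("chr%02d", seq_len(cfg$n_chrom)), each = cfg$snps_per_chrom)
  pos <- as.vector(vapply(seq_len(cfg$n_chrom), function(i)
    sort(sample.int(cfg$chrom_length_bp - 1000, cfg$snps_per_chrom)) + 500L,
    integer(cfg$snps_per_chrom)))
  pops <- sprintf("pop%02d", seq_len(cfg$n_pops))
  region_of_pop <- rep(paste0("region", seq_len(cfg$n_regions)),
                       length.out = cfg$n_pops)
  region_of_pop <- sort(region_of_pop)
  names(region_of_pop) <- pops

  p0 <- stats::runif(n_snp, 0.05, 0.95)
  region_p <- lapply(unique(region_of_pop), function(r) bn_draw(p0, cfg$fst_region))
  names(region_p) <- unique(region_of_pop)
  deme_p <- lapply(pops, function(pp) bn_draw(region_p[[region_of_pop[pp]]],
                                              cfg$fst_deme))
  names(deme_p) <- pops

  n_tot <- cfg$n_pops * cfg$n_ind
  geno <- matrix(NA_integer_, n_tot, n_snp)
  pop_of_ind <- rep(pops, each = cfg$n_ind)
  for (pp in pops) {
    rows <- which(pop_of_ind == pp)
    draws <- stats::rbinom(length(rows) * n_snp, 2,
                           rep(deme_p[[pp]], each = length(rows)))
    geno[rows, ] <- matrix(draws, length(rows), n_snp)
  }
  if (cfg$missing_rate > 0)
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_

  ad <- NULL
  if (cfg$simulate_ad) {
    depth <- matrix(stats::rnbinom(length(geno), mu = cfg$depth_mean,
                                   size = cfg$depth_size) + 1L,
                    nrow(geno), ncol(geno))
    refr <- matrix(0L, nrow(geno), ncol(geno))
    hom_ref <- which(!is.na(geno) & geno == 0L)
    refr[hom_ref] <- depth[hom_ref]
    het <- which(!is.na(geno) & geno == 1L)
    refr[het] <- stats::rbinom(length(het), depth[het], 0.5)
    refr[is.na(geno)] <- NA_integer_
    altm <- depth - refr
    altm[is.na(geno)] <- NA_integer_
    ad <- list(ref = refr, alt = altm)
  }

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_snp, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  snps <- data.frame(id = paste0(chrom, ":", pos), chrom = chrom,
                     pos = pos, ref = ref, alt = unname(alt),
                     tag_id = paste0("tag", seq_len(n_snp)),
                     stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_i%03d", pop_of_ind, sequence(rep(cfg$n_ind, cfg$n_pops))),
    population = pop_of_ind, stringsAsFactors = FALSE)
  gs <- geno_set(geno, snps, samples, ad = ad)
  truth <- list(ancestral_p = p0, deme_p = deme_p,
                region_of_pop = region_of_pop,
                islands = list(), inversion = NULL, seed = cfg$seed)
  structure(list(data = gs, truth = truth, config = cfg),
            class = "sim_dataset")
}

#' Inject a divergence island
#'
#' SNPs inside the span get allele-frequency differentials between the
#' affected and unaffected demes sized to a parametric two-group F_ST of
#' `fst`: frequencies are shifted to `pbar +/- sqrt(fst * pbar * (1 - pbar))`
#' (clamped to [0.02, 0.98]) and genotypes in the span are redrawn under
#' Hardy-Weinberg with the per-deme Balding-Nichols jitter of the baseline.
#' SNPs outside the span are untouched.
#'
#' @param sim a `sim_dataset`.
#' @param chrom,start_bp,end_bp island span.
#' @param fst target two-group parametric F_ST inside the island.
#' @param affected_pops character vector of affected demes; NULL = all demes
#'   of the first regional group.
#' @param seed RNG seed (default: derived from the baseline seed).
#' @return the modified `sim_dataset` with the island appended to the truth
#'   manifest.
#' @export
inject_divergence_island <- function(sim, chrom, start_bp, end_bp, fst,
                                     affected_pops = NULL, seed = NULL) {
  inv <- sim$truth$inversion
  if (!is.null(inv) && inv$chrom == chrom &&
      start_bp <= inv$end_bp && end_bp >= inv$start_bp)
    stop("island span overlaps the inversion span")
  set.seed(if (is.null(seed)) sim$truth$seed + 1000L + length(sim$truth$islands)
           else seed)
  x <- sim$data
  if (is.null(affected_pops)) {
    reg <- sim$truth$region_of_pop
    affected_pops <- names(reg)[reg == reg[[1]]]
  }
  stopifnot(all(affected_pops %in% x$samples$population))
  snp <- which(x$snps$chrom == chrom & x$snps$pos >= start_bp &
                 x$snps$pos <= end_bp)
  if (fst > 0 && length(snp)) {
    pbar <- sim$truth$ancestral_p[snp]
    delta <- sqrt(fst * pbar * (1 - pbar))
    p_aff <- pmin(pmax(pbar + delta, 0.02), 0.98)
    p_un <- pmin(pmax(pbar - delta, 0.02), 0.98)
    for (pp in unique(x$samples$population)) {
      rows <- which(x$samples$population == pp)
      base_p <- if (pp %in% affected_pops) p_aff else p_un
      pd <- bn_draw(base_p, sim$config$fst_deme)
      miss <- is.na(x$geno[rows, snp, drop = FALSE])
      draws <- stats::rbinom(length(rows) * length(snp), 2,
                             rep(pd, each = length(rows)))
      gnew <- matrix(as.integer(draws), length(rows), length(snp))
      gnew[miss] <- NA_integer_
      x$geno[rows, snp] <- gnew
    }
    x <- refresh_stats(x)
  }
  sim$data <- x
  sim$truth$islands <- c(sim$truth$islands, list(list(
    chrom = chrom, start_bp = start_bp, end_bp = end_bp, fst = fst,
    affected_pops = affected_pops,
    snp_ids = x$snps$id[snp])))
  sim
}

#' Inject a non-recombining haplotype block (putative inversion)
#'
#' Two haplotypes segregate in the span: at a `divergent_frac` fraction of
#' span SNPs the minor haplotype carries the alternate allele at frequency
#' 0.95 and the major haplotype at 0.03 (near-fixed differences); remaining
#' span SNPs keep their background genotypes. Individuals receive minor-
#' haplotype copies by seeded draws at frequency `f`: Binomial(2, f) when
#' minor homozygotes are allowed, otherwise heterozygous-carrier draws with
#' probability `2f` (expected haplotype frequency preserved, no minor
#' homozygotes). Genotypes at divergent SNPs are the sum of per-copy allele
#' draws, so heterozygous carriers read as dosage 1 across the block.
#'
#' @param sim a `sim_dataset`.
#' @param chrom,start_bp,end_bp block span.
#' @param f minor-haplotype frequency, <= 0.5.
#' @param allow_minor_homozygotes default FALSE.
#' @param divergent_frac fraction of span SNPs with near-fixed differences
#'   (default 0.85, which reproduces a block-wide mean r-squared near 0.3 at
#'   a 10% haplotype frequency).
#' @param seed RNG seed (default derived from the baseline seed).
#' @return the modified `sim_dataset`; truth gains `inversion` with the
#'   carrier list and the realized haplotype frequency.
#' @export
inject_inversion <- function(sim, chrom, start_bp, end_bp, f = 0.096,
                             allow_minor_homozygotes = FALSE,
                             divergent_frac = 0.85, seed = NULL) {
  if (f > 0.5) stop("the minor haplotype has frequency <= 0.5 by definition")
  for (isl in sim$truth$islands)
    if (isl$chrom == chrom && start_bp <= isl$end_bp && end_bp >= isl$start_bp)
      stop("inversion span overlaps an island span")
  set.seed(if (is.null(seed)) sim$truth$seed + 2000L else seed)
  x <- sim$data
  snp <- which(x$snps$chrom == chrom & x$snps$pos >= start_bp &
                 x$snps$pos <= end_bp)
  n <- nrow(x$geno)
  copies <- if (f == 0) integer(n)
  else if (allow_minor_homozygotes) stats::rbinom(n, 2, f)
  else as.integer(stats::runif(n) < 2 * f)
  div <- sort(sample(snp, round(divergent_frac * length(snp))))
  hi <- 0.95; lo <- 0.03
  if (f == 0) div <- integer(0)   # no carriers: leave the span untouched
  if (length(div)) {
    for (i in seq_len(n)) {
      m <- copies[i]
      miss <- is.na(x$geno[i, div])
      gnew <- stats::rbinom(length(div), m, hi) +
        stats::rbinom(length(div), 2L - m, lo)
      gnew[miss] <- NA_integer_
      x$geno[i, div] <- as.integer(gnew)
    }
    x <- refresh_stats(x)
  }
  sim$data <- x
  sim$truth$inversion <- list(
    chrom = chrom, start_bp = start_bp, end_bp = end_bp, f = f,
    allow_minor_homozygotes = allow_minor_homozygotes,
    carriers = x$samples$sample_id[copies > 0],
    copies = copies,
    realized_f = mean(copies) / 2,
    divergent_snp_ids = x$snps$id[div])
  sim
}

#' Simulate a complete dataset from a config
#'
#' [simulate_baseline] followed by the configured island and inversion
#' injections.
#'
#' @param cfg a [sim_config].
#' @return a `sim_dataset`.
#' @export
simulate_dataset <- function(cfg) {
  sim <- simulate_baseline(cfg)
  if (!is.null(cfg$inversion))
    sim <- do.call(inject_inversion, c(list(sim = sim), cfg$inversion))
  for (isl in cfg$islands)
    sim <- do.call(inject_divergence_island, c(list(sim = sim), isl))
  sim
}

#' Procedural lake raster and shoreline population coordinates
#'
#' Generates a lake-like water body on a grid with a land peninsula
#' descending from the northern shore, splitting the lake into two arms that
#' connect in the south; populations are placed along a U-shaped shoreline
#' path (stepping-stone layout), so cross-arm pairs have in-water distances
#' exceeding their straight-line distances.
#'
#' @param n_pops number of populations to place.
#' @param nrow_,ncol_ grid size (defaults 40 x 60).
#' @param cellsize cell size (default 1).
#' @return list: `raster` (a [resistance_raster]), `coords` (data.frame
#'   `pop`, `x`, `y`).
#' @export
simulate_raster_and_coords <- function(n_pops, nrow_ = 40, ncol_ = 60,
                                       cellsize = 1) {
  water <- matrix(FALSE, nrow_, ncol_)
  water[5:(nrow_ - 4), 5:(ncol_ - 4)] <- TRUE
  pen_col <- round(ncol_ / 2)
  water[5:(nrow_ - 10), (pen_col - 1):(pen_col + 1)] <- FALSE  # peninsula
  # U-shaped shoreline path: down the west arm, along the south, up the east
  west_x <- 7; east_x <- ncol_ - 7; south_y <- nrow_ - 7; north_y <- 7
  path <- rbind(
    cbind(west_x, seq(north_y, south_y)),
    cbind(seq(west_x + 1, east_x - 1), south_y),
    cbind(east_x, seq(south_y, north_y)))
  if (n_pops > nrow(path)) stop("cannot place all populations on water")
  sel <- round(seq(1, nrow(path), length.out = n_pops))
  coords <- data.frame(pop = sprintf("pop%02d", seq_len(n_pops)),
                       x = (path[sel, 1] - 0.5) * cellsize,
                       y = (path[sel, 2] - 0.5) * cellsize)
  list(raster = resistance_raster(water, cellsize = cellsize),
       coords = coords)
}

#' Write a simulated dataset to disk
#'
#' Emits the VCF, the sample-to-population map, the ground-truth manifest
#' (JSON) and, when supplied, the resistance raster (ESRI ASCII) and
#' coordinates (TSV).
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @param spatial optional list from [simulate_raster_and_coords].
#' @return named vector of the written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, spatial = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$data, paths["vcf"])
  write_popmap(sim$data, paths["popmap"])
  truth <- sim$truth
  truth$deme_p <- NULL; truth$ancestral_p <- NULL  # bulky; reproducible from seed
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(spatial)) {
    paths["raster"] <- file.path(dir, "raster.asc")
    paths["coords"] <- file.path(dir, "coords.tsv")
    write_ascii_grid(spatial$raster, paths["raster"])
    utils::write.table(spatial$coords, paths["coords"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
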