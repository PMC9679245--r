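# The generator: determinism, ground truth consistency, calibration.

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_pops = 3, n_ind = 8, n_chrom = 2, snps_per_chrom = 40,
                    chrom_length_bp = 1e6, seed = 91,
                    islands = list(list(chrom = "chr01", start_bp = 2e5,
                                        end_bp = 4e5, fst = 0.2,
                                        affected_pops = "pop01")),
                    inversion = list(chrom = "chr02", start_bp = 2e5,
                                     end_bp = 6e5, f = 0.2,
                                     allow_minor_homozygotes = FALSE))
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_dataset(cfg)$data, f1)
  write_vcf(simulate_dataset(cfg)$data, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth manifest intervals lie inside chromosomes and never overlap", {
  cfg <- sim_config(n_pops = 4, n_ind = 6, n_chrom = 4, snps_per_chrom = 50,
                    chrom_length_bp = 60e6, seed = 92)   # default islands + inversion
  sim <- simulate_dataset(cfg)
  spans <- c(lapply(sim$truth$islands, function(i)
    list(chrom = i$chrom, s = i$start_bp, e = i$end_bp)),
    list(list(chrom = sim$truth$inversion$chrom,
              s = sim$truth$inversion$start_bp,
              e = sim$truth$inversion$end_bp)))
  for (sp in spans) {
    expect_gte(sp$s, 0)
    expect_lte(sp$e, 60e6)
  }
  for (i in seq_along(spans)) for (j in seq_along(spans)) if (i < j) {
    same <- spans[[i]]$chrom == spans[[j]]$chrom
    if (same)
      expect_true(spans[[i]]$e < spans[[j]]$s || spans[[j]]$e < spans[[i]]$s)
  }
})

test_that("island-model theta matches the simulated differentiation level", {
  # single-level model: expected multi-locus theta = fst_deme
  target <- 0.01
  thetas <- sapply(1:4, function(s) {
    cfg <- sim_config(n_pops = 4, n_ind = 25, n_chrom = 2,
                      snps_per_chrom = 600, chrom_length_bp = 30e6,
                      fst_deme = target, fst_region = 0, missing_rate = 0,
                      simulate_ad = FALSE, islands = list(), inversion = NULL,
                      seed = 900 + s)
    wc_fst(simulate_dataset(cfg)$data)$theta
  })
  mc_se <- sd(thetas) / sqrt(length(thetas))
  expect_lt(abs(mean(thetas) - target), 3 * mc_se + 0.001)
})

test_that("high migration (low F) gives theta < 0.01 and one deme gives ~0", {
  cfg <- sim_config(n_pops = 2, n_ind = 30, n_chrom = 1, snps_per_chrom = 800,
                    chrom_length_bp = 30e6, fst_deme = 0.001, fst_region = 0,
                    missing_rate = 0, simulate_ad = FALSE, islands = list(),
                    inversion = NULL, seed = 93)
  expect_lt(wc_fst(simulate_dataset(cfg)$data)$theta, 0.01)
  cfg1 <- sim_config(n_pops = 1, n_ind = 40, n_chrom = 1, snps_per_chrom = 500,
                     chrom_length_bp = 30e6, fst_deme = 0, fst_region = 0,
                     missing_rate = 0, simulate_ad = FALSE, islands = list(),
                     inversion = NULL, seed = 94)
  x <- simulate_dataset(cfg1)$data
  x$samples$population <- rep(c("u", "v"), 20)   # arbitrary label split
  expect_lt(abs(wc_fst(x)$theta), 0.005)
})

test_that("a zero-differential island leaves frequencies centered; a strong island is recovered", {
  base_cfg <- sim_config(n_pops = 4, n_ind = 20, n_chrom = 2,
                         snps_per_chrom = 400, chrom_length_bp = 30e6,
                         fst_deme = 0.003, fst_region = 0, missing_rate = 0,
                         simulate_ad = FALSE, islands = list(),
                         inversion = NULL, seed = 95)
  sim <- simulate_baseline(base_cfg)
  sim0 <- inject_divergence_island(sim, "chr01", 10e6, 14e6, fst = 0,
                                   affected_pops = "pop01")
  expect_identical(sim0$data$geno, sim$data$geno)   # differential 0: unchanged
  sim1 <- inject_divergence_island(sim, "chr01", 10e6, 14e6, fst = 0.25,
                                   affected_pops = "pop01")
  in_span <- sim1$data$snps$chrom == "chr01" &
    sim1$data$snps$pos >= 10e6 & sim1$data$snps$pos <= 14e6
  th_in <- wc_fst(sim1$data, pops = c("pop01", "pop02"), snp = which(in_span))$theta
  th_out <- wc_fst(sim1$data, pops = c("pop01", "pop02"), snp = which(!in_span))$theta
  expect_gt(th_in, 5 * max(th_out, 0.001))
  # the affected population is elevated against every other population
  for (other in c("pop02", "pop03", "pop04")) {
    expect_gt(wc_fst(sim1$data, pops = c("pop01", other),
                     snp = which(in_span))$theta, 0.1)
  }
  expect_lt(wc_fst(sim1$data, pops = c("pop02", "pop03"),
                   snp = which(in_span))$theta, 0.05)
})

test_that("inversion injection respects f and the no-minor-homozygote rule", {
  cfg <- sim_config(n_pops = 4, n_ind = 50, n_chrom = 1, snps_per_chrom = 500,
                    chrom_length_bp = 30e6, fst_deme = 0.002, fst_region = 0,
                    missing_rate = 0, simulate_ad = FALSE, islands = list(),
                    inversion = NULL, seed = 96)
  sim <- simulate_baseline(cfg)
  sim0 <- inject_inversion(sim, "chr01", 5e6, 12e6, f = 0)
  expect_identical(sim0$data$geno, sim$data$geno)
  sim1 <- inject_inversion(sim, "chr01", 5e6, 12e6, f = 0.1,
                           allow_minor_homozygotes = FALSE)
  expect_true(all(sim1$truth$inversion$copies <= 1L))
  expect_equal(sim1$truth$inversion$realized_f,
               mean(sim1$truth$inversion$copies) / 2)
  # block LD strongly elevated relative to background
  div <- sim1$truth$inversion$divergent_snp_ids
  gdiv <- sim1$data$geno[, match(div, sim1$data$snps$id)[1:40]]
  r2b <- cor(gdiv)^2
  out <- which(!(sim1$data$snps$id %in% div))[1:40]
  r2o <- cor(sim1$data$geno[, out])^2
  expect_gt(mean(r2b[upper.tri(r2b)]), 0.2)
  expect_lt(mean(r2o[upper.tri(r2o)], na.rm = TRUE), 0.05)
  expect_error(inject_inversion(sim, "chr01", 1e6, 2e6, f = 0.6), "0.5")
})

test_that("island and inversion spans must not overlap", {
  cfg <- sim_config(n_pops = 2, n_ind = 6, n_chrom = 1, snps_per_chrom = 60,
                    chrom_length_bp = 10e6, islands = list(), inversion = NULL,
                    seed = 97)
  sim <- simulate_baseline(cfg)
  sim <- inject_inversion(sim, "chr01", 2e6, 4e6, f = 0.2)
  expect_error(inject_divergence_island(sim, "chr01", 3e6, 5e6, fst = 0.2,
                                        affected_pops = "pop01"),
               "overlaps the inversion")
  sim2 <- simulate_baseline(cfg)
  sim2 <- inject_divergence_island(sim2, "chr01", 2e6, 4e6, fst = 0.2,
                                   affected_pops = "pop01")
  expect_error(inject_inversion(sim2, "chr01", 3e6, 5e6, f = 0.2),
               "overlaps an island")
})

test_that("the procedural lake has two arms with longer in-water paths", {
  sp <- simulate_raster_and_coords(10)
  d <- least_cost_distances(sp$raster, sp$coords)
  # cross-arm pair: first and last populations sit near the two arm tops
  straight <- sqrt((sp$coords$x[1] - sp$coords$x[10])^2 +
                   (sp$coords$y[1] - sp$coords$y[10])^2)
  expect_gt(d[1, 10], straight * 1.2)
  # same-arm neighbours are close to straight-line
  straight12 <- sqrt((sp$coords$x[1] - sp$coords$x[2])^2 +
                     (sp$coords$y[1] - sp$coords$y[2])^2)
  expect_lt(d[1, 2], straight12 * 1.3)
  expect_error(simulate_raster_and_coords(10000), "cannot place")
})

test_that("written datasets reload through the standard readers", {
  cfg <- sim_config(n_pops = 2, n_ind = 5, n_chrom = 1, snps_per_chrom = 30,
                    chrom_length_bp = 1e6, islands = list(), inversion = NULL,
                    seed = 98)
  sim <- simulate_dataset(cfg)
  dir <- tempfile()
  sp <- simulate_raster_and_coords(2)
  paths <- write_sim_dataset(sim, dir, spatial = sp)
  x <- read_vcf(paths["vcf"], popmap = paths["popmap"])
  expect_identical(unname(x$geno), unname(sim$data$geno))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$seed, 98)
  r <- read_ascii_grid(paths["raster"])
  expect_identical(r$water, unname(sp$raster$water))
})
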