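# LD clumping, K selection, the PCA Mahalanobis scan, q-values.

test_that("clumping keeps the higher-MAF SNP of a duplicated pair", {
  set.seed(51)
  base <- hwe_geno(40, 0.3)
  other <- hwe_geno(40, 0.45)
  m <- cbind(base, base, other)   # columns 1-2 duplicated, col 2 pos later
  x <- make_gs(m)
  ts <- ld_clump_thin(x, thin_r2 = 0.2, window_snps = 10, min_mac = 1,
                      min_run = 100)
  expect_equal(length(ts$keep), 2L)
  # the duplicated pair contributes exactly one SNP
  expect_equal(sum(ts$keep %in% 1:2), 1L)
})

test_that("mutually independent SNPs are all retained in one iteration", {
  set.seed(52)
  m <- matrix(hwe_geno(60 * 30, 0.5), 60, 30)
  x <- make_gs(m)
  ts <- ld_clump_thin(x, min_mac = 1, min_run = 100)
  expect_equal(ts$keep, seq_len(30))
  expect_equal(ts$n_iter, 1L)
})

test_that("a perfect-LD block collapses to one SNP per clump window", {
  set.seed(53)
  block <- hwe_geno(50, 0.4)
  m <- cbind(matrix(rep(block, 20), 50, 20),
             matrix(hwe_geno(50 * 10, 0.5), 50, 10))
  x <- make_gs(m)
  ts <- ld_clump_thin(x, thin_r2 = 0.2, window_snps = 25, min_mac = 1,
                      min_run = 100)
  # brute-force greedy oracle: highest-MAF block SNP removes the other 19
  expect_equal(sum(ts$keep <= 20), 1L)
  expect_true(all(21:30 %in% ts$keep))
})

test_that("scree K finds simulated structure and honors the override", {
  cfg3 <- sim_config(n_pops = 3, n_ind = 30, n_chrom = 2, snps_per_chrom = 800,
                     chrom_length_bp = 30e6, fst_deme = 0.05, fst_region = 0,
                     missing_rate = 0.02, simulate_ad = FALSE,
                     islands = list(), inversion = NULL, seed = 54)
  x3 <- simulate_dataset(cfg3)$data
  expect_equal(choose_k_scree(x3)$K, 2L)     # 3 demes -> 2 axes

  cfg1 <- sim_config(n_pops = 1, n_ind = 60, n_chrom = 2, snps_per_chrom = 800,
                     chrom_length_bp = 30e6, fst_deme = 0, fst_region = 0,
                     missing_rate = 0.02, simulate_ad = FALSE,
                     islands = list(), inversion = NULL, seed = 55)
  x1 <- simulate_dataset(cfg1)$data
  expect_equal(choose_k_scree(x1)$K, 1L)     # panmixia -> no elbow beyond 1

  expect_equal(choose_k_scree(x1, override = 4)$K, 4L)
  expect_error(choose_k_scree(x1, k_max = 1), "k_max")
})

test_that("scan D2 equals an explicit least-squares computation on a toy", {
  set.seed(56)
  m <- matrix(sample(c(0L, 1L, 2L), 8 * 6, replace = TRUE), 8, 6)
  x <- make_gs(m)
  sc <- pcadapt_scan(x, K = 2, min_maf = 0, cov_method = "classical")
  # by hand: scale, SVD scores, per-SNP regression z, classical Mahalanobis
  n <- 8
  p <- colMeans(m) / 2
  z <- sweep(sweep(m, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(z)
  U <- sv$u[, 1:2]
  zsc <- matrix(0, 2, 6)
  for (j in 1:6) {
    fit <- lm.fit(U, z[, j])
    sigma2 <- sum(fit$residuals^2) / (n - 2)
    zsc[, j] <- fit$coefficients / sqrt(sigma2)   # U is orthonormal
  }
  d2 <- stats::mahalanobis(t(zsc), colMeans(t(zsc)), stats::cov(t(zsc)))
  expect_equal(unname(sc$table$D2), unname(d2), tolerance = 1e-8)
})

test_that("SNPs below the MAF floor get missing p/q and are never outliers", {
  set.seed(57)
  m <- cbind(matrix(hwe_geno(50 * 20, 0.4), 50, 20),
             c(rep(1L, 3), rep(0L, 47)))    # maf = 0.03
  x <- make_gs(m)
  sc <- pcadapt_scan(x, K = 1, min_maf = 0.05)
  expect_true(is.na(sc$table$p[21]))
  expect_true(is.na(sc$table$q[21]))
  expect_false(sc$table$outlier[21])
  expect_true(all(!is.na(sc$table$p[1:20])))
})

test_that("D2 is stable under ref/alt flips", {
  # flipping a SNP negates its z-score; D2 is unchanged up to the (small,
  # O(1/sqrt(n_snp))) estimated center of the z distribution
  set.seed(58)
  m <- matrix(hwe_geno(60 * 500, 0.3), 60, 500)
  x <- make_gs(m)
  sc <- pcadapt_scan(x, K = 1, min_maf = 0, cov_method = "classical")
  y <- x
  y$geno[, 7] <- 2L - y$geno[, 7]
  y <- refresh_stats(y)
  sc2 <- pcadapt_scan(y, K = 1, min_maf = 0, cov_method = "classical")
  expect_gt(cor(sc2$table$D2, sc$table$D2), 0.999)
  expect_lt(abs(sc2$table$D2[7] - sc$table$D2[7]), 0.25)
  expect_identical(sc2$table$outlier, sc$table$outlier)
})

test_that("BH q-values match the hand formula and edge cases", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(compute_qvalues(p, method = "bh"),
               c(0.004, 0.02, 4 * 0.02 / 3, 0.8))
  expect_equal(compute_qvalues(p, method = "bh"), oracle_bh(p))
  # ties: all p equal 0.5 -> all q = 0.5 under BH
  expect_equal(compute_qvalues(rep(0.5, 4), method = "bh"), rep(0.5, 4))
  # single p -> q = p
  expect_equal(compute_qvalues(0.3), 0.3)
  # missing propagates; all-missing errors
  q <- compute_qvalues(c(0.01, NA, 0.5), method = "bh")
  expect_true(is.na(q[2]) && !anyNA(q[-2]))
  expect_error(compute_qvalues(c(NA_real_, NA_real_)), "missing")
  expect_error(compute_qvalues(c(0, 0.5)), "0, 1")
})

test_that("Storey q-values track BH scaled by pi0 and stay monotone", {
  set.seed(59)
  p <- c(runif(900), runif(100, 0, 0.001))
  qs <- compute_qvalues(p, method = "storey")
  qb <- compute_qvalues(p, method = "bh")
  expect_true(all(qs <= qb + 1e-12))          # pi0 <= 1
  o <- order(p)
  expect_true(all(diff(qs[o]) >= -1e-12))     # monotone in p
})

test_that("outlier sets combine as a union with scope provenance", {
  set.seed(60)
  m <- matrix(hwe_geno(30 * 40, 0.4), 30, 40)
  x <- make_gs(m)
  mk_scan <- function(out_idx, scope) {
    sc <- pcadapt_scan(x, K = 1, min_maf = 0, scope = scope,
                       cov_method = "classical")
    sc$table$outlier <- seq_len(40) %in% out_idx
    sc
  }
  a <- mk_scan(c(1, 2, 3), "full")
  b <- mk_scan(c(3, 10, 11, 12), "east")
  u <- combine_outlier_sets(list(a, b))
  expect_equal(nrow(u), 6L)
  expect_equal(u$scopes[u$id == x$snps$id[3]], "full,east")
  # idempotent on identical sets
  expect_equal(nrow(combine_outlier_sets(list(a, a))), 3L)
  # mismatched universes error
  y <- subset_geno(x, snp = 1:20)
  c_scan <- pcadapt_scan(y, K = 1, min_maf = 0, scope = "sub",
                         cov_method = "classical")
  expect_error(combine_outlier_sets(list(a, c_scan)), "universe")
})
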