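# QC filter cascade, thinning, paralog filter, relatedness, tag filters.

test_that("filter cascade applies the three rules in order", {
  # SNP with mac = 2 must go at min_mac = 3
  set.seed(1)
  m <- cbind(c(1L, 1L, rep(0L, 8)),                  # mac 2
             c(2L, 2L, 1L, rep(0L, 7)),              # mac 5
             rep(c(0L, 1L), 5))                      # mac 5
  x <- make_gs(m)
  fc <- filter_cascade(x, min_mac = 3, min_snp_call = 0, max_ind_missing = 1)
  expect_equal(ncol(fc$data$geno), 2L)
  expect_equal(fc$report$removed, c(1L, 0L, 0L))

  # fully genotyped individuals are never removed at max_ind_missing = 0.5
  expect_equal(nrow(fc$data$geno), 10L)
})

test_that("cascade equals brute-force rule transcription on a toy with missing cells", {
  set.seed(7)
  m <- matrix(sample(c(0L, 1L, 2L, NA), 100, replace = TRUE,
                     prob = c(.4, .3, .2, .1)), 10, 10)
  x <- make_gs(m)
  min_mac <- 3; min_call <- 0.7; max_miss <- 0.4
  # brute force: rule 1, rule 2 on the original matrix, then rule 3 on kept SNPs
  keep_snp <- logical(10)
  for (j in 1:10) {
    g <- m[, j]
    nc <- sum(!is.na(g))
    alt <- sum(g, na.rm = TRUE)
    mac <- min(alt, 2 * nc - alt)
    keep_snp[j] <- mac >= min_mac && nc / 10 >= min_call
  }
  keep_ind <- rowMeans(is.na(m[, keep_snp, drop = FALSE])) <= max_miss
  fc <- filter_cascade(x, min_mac, min_call, max_miss)
  expect_equal(fc$data$snps$id, x$snps$id[keep_snp])
  expect_equal(fc$data$samples$sample_id, x$samples$sample_id[keep_ind])
})

test_that("filter cascade is idempotent", {
  cfg <- sim_config(n_pops = 2, n_ind = 12, n_chrom = 1, snps_per_chrom = 80,
                    chrom_length_bp = 1e6, missing_rate = 0.25,
                    islands = list(), inversion = NULL, seed = 3)
  x <- simulate_dataset(cfg)$data
  f1 <- filter_cascade(x, 3, 0.8, 0.3)
  f2 <- filter_cascade(f1$data, 3, 0.8, 0.3)
  expect_identical(f2$data$geno, f1$data$geno)
  expect_true(all(f2$report$removed == 0))
})

test_that("cascade errors (with report) when everything is removed", {
  x <- make_gs(cbind(c(0L, 1L), c(0L, 0L)))
  err <- tryCatch(filter_cascade(x, min_mac = 5), error = identity)
  expect_match(conditionMessage(err), "all SNPs removed")
  expect_s3_class(err$report, "data.frame")
})

test_that("distance thinning keeps the greedy set", {
  snps <- data.frame(chrom = "chr1", pos = c(100L, 300L, 600L))
  expect_equal(thin_by_distance(snps, 400), c(1L, 3L))
  # one SNP per chromosome: all kept
  snps2 <- data.frame(chrom = c("chr1", "chr2", "chr3"), pos = c(5L, 5L, 5L))
  expect_equal(thin_by_distance(snps2, 400), 1:3)
  expect_error(thin_by_distance(data.frame(chrom = "c", pos = c(9L, 2L)), 400),
               "sorted")
  # random positions vs the brute-force greedy oracle
  set.seed(11)
  pos <- sort(sample.int(20000, 50))
  chrom <- rep(c("chr1", "chr2"), c(30, 20))
  snps3 <- data.frame(chrom = chrom, pos = c(sort(pos[1:30]), sort(pos[31:50])))
  got <- thin_by_distance(snps3, 800)
  expect_equal(got, oracle_thin(snps3$chrom, snps3$pos, 800))
  # property: all successive same-chromosome gaps >= min_bp
  kept <- snps3[got, ]
  for (ch in unique(kept$chrom))
    expect_true(all(diff(kept$pos[kept$chrom == ch]) >= 800))
})

test_that("HDPlot removes excess-heterozygosity and read-ratio outliers", {
  # 10 individuals, 3 SNPs: H = 0.6 at SNP1; monomorphic SNP2;
  # SNP3 with 10 hets totalling 600 ref / 400 alt reads -> D = 200/sqrt(1000)
  g <- cbind(c(rep(1L, 6), rep(0L, 4)), rep(0L, 10), rep(1L, 10))
  ref <- cbind(ifelse(g[, 1] == 1L, 5L, 10L), 10L, 60L)
  alt <- cbind(ifelse(g[, 1] == 1L, 5L, 0L), 0L, 40L)
  x <- make_gs(g, ad = list(ref = ref, alt = alt))
  hd <- hdplot_filter(x, max_h = 0.55, max_abs_d = 5)
  expect_equal(hd$table$H, c(0.6, 0, 1))
  expect_equal(hd$table$D[2], 0)
  expect_equal(hd$table$D[3], 200 / sqrt(1000))
  expect_equal(hd$keep, 2L)   # SNP1 fails H, SNP3 fails |D| = 6.32 > 5
})

test_that("HDPlot D is antisymmetric under ref/alt swap, H invariant", {
  cfg <- sim_config(n_pops = 1, n_ind = 30, n_chrom = 1, snps_per_chrom = 40,
                    chrom_length_bp = 1e6, missing_rate = 0.05,
                    islands = list(), inversion = NULL, seed = 5)
  x <- simulate_dataset(cfg)$data
  hd <- hdplot_filter(x)$table
  y <- x
  y$geno <- 2L - y$geno
  y$ad <- list(ref = x$ad$alt, alt = x$ad$ref)
  y <- refresh_stats(y)
  hd_flip <- hdplot_filter(y)$table
  expect_equal(hd_flip$H, hd$H)
  expect_equal(hd_flip$D, -hd$D)
})

test_that("relatedness flags duplicates and matches the formula on a toy", {
  set.seed(21)
  p <- runif(800, 0.1, 0.9)
  g1 <- hwe_geno(800, p)
  m <- rbind(g1, g1,                                   # duplicated individual
             t(replicate(38, rbinom(800, 2, p))))      # 40-sample panel
  x <- make_gs(m)
  rel <- relatedness_dedup(x, min_maf = 0.05, threshold = 0.9)
  dup <- rel[rel$sample_1 == "ind001" & rel$sample_2 == "ind002", ]
  expect_true(dup$flagged)
  expect_gt(dup$relatedness, 0.9)

  # independently drawn individuals stay far below the threshold
  others <- rel[rel$sample_1 != "ind001" & rel$sample_2 != "ind002" &
                  rel$sample_1 != "ind002", ]
  expect_true(all(abs(others$relatedness) < 0.2))
  expect_false(any(others$flagged))

  # 4 x 3 toy equals a direct transcription of the estimator
  m3 <- rbind(c(0L, 1L, 2L), c(1L, 1L, 0L), c(2L, 0L, 1L), c(0L, 2L, 2L))
  x3 <- make_gs(m3)
  rel3 <- relatedness_dedup(x3, min_maf = 0, threshold = 0.9)
  p3 <- colMeans(m3) / 2
  expect_equal(rel3$relatedness[1], oracle_relatedness(m3[1, ], m3[2, ], p3))
  expect_equal(rel3$relatedness[6], oracle_relatedness(m3[3, ], m3[4, ], p3))
})

test_that("relatedness errors when no SNP passes the MAF filter", {
  x <- make_gs(rbind(c(0L, 0L), c(0L, 1L)))
  expect_error(relatedness_dedup(x, min_maf = 0.4), "MAF filter")
})

test_that("haplotype-count filter removes SNPs on over-split tags", {
  snps <- data.frame(tag_id = c("t1", "t1", "t2", NA))
  counts <- c(t1 = 11L, t2 = 2L)
  expect_equal(haplotype_count_filter(counts, snps, max_haps = 10), 3:4)
  counts2 <- c(t1 = 1L, t2 = 1L)
  expect_equal(haplotype_count_filter(counts2, snps, max_haps = 10), 1:4)
  # mixed toy equals the set-comprehension rule
  snps3 <- data.frame(tag_id = c("a", "b", "a", "c", NA, "b"))
  cnt3 <- c(a = 12L, b = 3L, c = 11L)
  bad <- names(cnt3)[cnt3 > 10]
  expect_equal(haplotype_count_filter(cnt3, snps3, 10),
               which(is.na(snps3$tag_id) | !(snps3$tag_id %in% bad)))
  expect_error(haplotype_count_filter(c(a = 0L), snps, 10), ">= 1")
})

test_that("one SNP per tag keeps the first in position order", {
  snps <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                     tag_id = c("t1", "t1", NA, "t2"))
  expect_equal(one_snp_per_tag(snps), c(1L, 3L, 4L))
})
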