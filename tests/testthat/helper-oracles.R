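# Independent brute-force oracles and small-fixture builders. Everything here
# is written as a literal transcription of the published formulas / rules,
# deliberately naive (explicit loops, no shared code with the package
# internals), so it can serve as a cross-check.

# Build a geno_set from a plain matrix (rows = individuals).
make_gs <- function(m, pops = NULL, chrom = NULL, pos = NULL, ad = NULL,
                    tag_id = NULL) {
  m <- as.matrix(m)
  n_snp <- ncol(m)
  if (is.null(chrom)) chrom <- rep("chr1", n_snp)
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000L
  if (is.null(pops)) pops <- rep("popA", nrow(m))
  snps <- data.frame(id = paste0(chrom, ":", pos), chrom = chrom,
                     pos = as.integer(pos), ref = "A", alt = "C",
                     tag_id = if (is.null(tag_id)) NA_character_ else tag_id,
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("ind%03d", seq_len(nrow(m))),
                        population = pops, stringsAsFactors = FALSE)
  geno_set(m, snps, samples, ad = ad)
}

# HWE genotype draws at allele frequency p.
hwe_geno <- function(n, p) stats::rbinom(n, 2, p)

# Weir & Cockerham (1984) per-locus variance components, literal equations,
# diploid, one locus, r populations given as a list of genotype vectors
# (dosages 0/1/2, NA = missing).
oracle_wc84_locus <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n <- sapply(geno_by_pop, function(g) sum(!is.na(g)))
  p <- sapply(geno_by_pop, function(g) sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))))
  h <- sapply(geno_by_pop, function(g) sum(g == 1, na.rm = TRUE) / sum(!is.na(g)))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Multi-locus theta, ratio of sums over loci; pop = label vector.
oracle_wc84_theta <- function(g, pop) {
  pops <- unique(pop)
  num <- den <- 0
  for (j in seq_len(ncol(g))) {
    by_pop <- lapply(pops, function(pp) g[pop == pp, j])
    if (any(sapply(by_pop, function(v) sum(!is.na(v))) == 0)) next
    comp <- oracle_wc84_locus(by_pop)
    if (any(is.na(comp))) next
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  unname(num / den)
}

# Squared Pearson correlation of two dosage vectors, complete pairs only.
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  (num / den)^2
}

# Benjamini-Hochberg by the textbook formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) q[o[i]] <- p[o[i]] * m / i
  # enforce monotonicity from the largest p downwards
  for (i in (m - 1):1) q[o[i]] <- min(q[o[i]], q[o[i + 1]])
  pmin(q, 1)
}

# Exhaustive Mantel test over all permutations (small n only).
oracle_mantel_exhaustive <- function(d1, d2) {
  n <- nrow(d1)
  perms <- gtools_permutations(n)
  lt <- lower.tri(d1)
  r_obs <- stats::cor(d1[lt], d2[lt])
  r_null <- apply(perms, 1, function(pp) stats::cor(d1[lt], d2[pp, pp][lt]))
  # identity permutation is part of the null set
  list(r = r_obs, p = mean(r_null >= r_obs))
}

# All permutations of 1..n (tiny n), no external dependency.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Exact one-sided paired Wilcoxon signed-rank p by enumeration of all 2^n
# sign assignments (no zeros, no ties assumed).
oracle_wilcoxon_exact <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  total <- 0
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    w <- sum(rk[signs == 1])
    total <- total + 1
    if (w >= w_obs) hits <- hits + 1
  }
  hits / total
}

# Brute-force sliding-window candidate enumeration for one chromosome.
oracle_windows <- function(flags, window, step, min_out) {
  m <- length(flags)
  if (m < window) return(data.frame(start_ord = integer(), n = integer()))
  starts <- seq(0, m - window, by = step)
  res <- data.frame(start_ord = starts,
                    n = sapply(starts, function(s) sum(flags[(s + 1):(s + window)])))
  res[res$n >= min_out, , drop = FALSE]
}

# Greedy distance thinning transcription.
oracle_thin <- function(chrom, pos, min_bp) {
  keep <- integer(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (pos[i] - last >= min_bp) {
        keep <- c(keep, i)
        last <- pos[i]
      }
    }
  }
  keep
}

# Yang-type relatedness between two dosage vectors given frequencies p.
oracle_relatedness <- function(x1, x2, p) {
  ok <- !is.na(x1) & !is.na(x2)
  mean((x1[ok] - 2 * p[ok]) * (x2[ok] - 2 * p[ok]) / (2 * p[ok] * (1 - p[ok])))
}
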