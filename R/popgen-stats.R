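#' Per-population diversity statistics
#'
#' For each SNP and population: observed heterozygosity `H_O` is the
#' proportion of called genotypes that are heterozygous, and expected
#' heterozygosity uses the small-sample unbiased estimator
#' `H_E = 2 p (1 - p) * 2n / (2n - 1)` with `n` the number of called
#' individuals. Population values are means over SNPs polymorphic in the
#' whole dataset, and the inbreeding coefficient is computed from those
#' means: `F_IS = 1 - mean(H_O) / mean(H_E)` (the summary-file convention of
#' common RADseq genotyping pipelines). A population monomorphic at every
#' SNP gets `H_E = 0` and missing `F_IS`.
#'
#' @param x a [geno_set].
#' @return data.frame: `population`, `n_ind`, `h_exp`, `h_obs`, `f_is`.
#' @export
diversity_stats <- function(x) {
  poly <- x$snps$mac > 0
  g <- x$geno[, poly, drop = FALSE]
  pops <- sort(unique(x$samples$population))
  out <- data.frame(population = pops, n_ind = NA_integer_,
                    h_exp = NA_real_, h_obs = NA_real_, f_is = NA_real_)
  for (i in seq_along(pops)) {
    gp <- g[x$samples$population == pops[i], , drop = FALSE]
    n <- colSums(!is.na(gp))
    if (all(n == 0)) stop("population ", pops[i], " has no called genotypes")
    use <- n > 0
    ho <- colSums(gp == 1L, na.rm = TRUE)[use] / n[use]
    p <- colSums(gp, na.rm = TRUE)[use] / (2 * n[use])
    he <- 2 * p * (1 - p) * (2 * n[use]) / (2 * n[use] - 1)
    mean_he <- mean(he)
    mean_ho <- mean(ho)
    out$n_ind[i] <- nrow(gp)
    out$h_exp[i] <- mean_he
    out$h_obs[i] <- mean_ho
    out$f_is[i] <- if (mean_he > 0) 1 - mean_ho / mean_he else NA_real_
  }
  out
}

# Per-SNP Weir-Cockerham (1984) variance components for r populations.
# Returns a 3-row matrix (a, b, c) x SNPs. SNPs where any population has no
# called genotype are dropped (column of NA).
wc_components <- function(g, pop) {
  pops <- unique(pop)
  r <- length(pops)
  if (r < 2) stop("need at least 2 populations")
  nmat <- pmat <- hmat <- matrix(NA_real_, r, ncol(g))
  for (i in seq_len(r)) {
    gp <- g[pop == pops[i], , drop = FALSE]
    if (nrow(gp) < 2) stop("population ", pops[i], " has fewer than 2 individuals")
    nmat[i, ] <- colSums(!is.na(gp))
    pmat[i, ] <- ifelse(nmat[i, ] > 0, colSums(gp, na.rm = TRUE) / (2 * nmat[i, ]), NA)
    hmat[i, ] <- ifelse(nmat[i, ] > 0, colSums(gp == 1L, na.rm = TRUE) / nmat[i, ], NA)
  }
  ok <- colSums(nmat > 0) == r & colSums(nmat) > r  # every pop called, nbar > 1
  nbar <- colMeans(nmat)
  sn2 <- colSums(nmat^2)
  nc <- (r * nbar - sn2 / (r * nbar)) / (r - 1)
  pbar <- colSums(nmat * pmat) / (r * nbar)
  s2 <- colSums(nmat * sweep(pmat, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(nmat * hmat) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- b[!ok] <- cc[!ok] <- NA_real_
  rbind(a = a, b = b, c = cc)
}

#' Multi-locus Weir-Cockerham theta (F_ST)
#'
#' Per-SNP variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) following Weir & Cockerham
#' (1984), combined as the ratio of sums `theta = sum(a) / sum(a + b + c)`
#' (the "weighted" multi-locus estimator). Monomorphic SNPs contribute zero
#' to both sums; negative estimates are reported as-is.
#'
#' @param x a [geno_set].
#' @param pops optional character vector of population codes to restrict to
#'   (e.g. one pair); default all populations.
#' @param snp optional SNP index to restrict to.
#' @return list: `theta` (scalar), `components` (3 x n_snp matrix),
#'   `per_locus` (per-SNP a/(a+b+c), NA where undefined).
#' @export
wc_fst <- function(x, pops = NULL, snp = NULL) {
  keep <- if (is.null(pops)) rep(TRUE, nrow(x$samples)) else x$samples$population %in% pops
  if (!is.null(pops) && length(unique(x$samples$population[keep])) < length(unique(pops)))
    stop("population(s) absent from dataset")
  g <- x$geno[keep, , drop = FALSE]
  if (!is.null(snp)) g <- g[, snp, drop = FALSE]
  comp <- wc_components(g, x$samples$population[keep])
  tot <- colSums(comp)
  theta <- sum(comp["a", ], na.rm = TRUE) / sum(tot, na.rm = TRUE)
  per_locus <- ifelse(!is.na(tot) & tot != 0, comp["a", ] / tot, NA_real_)
  list(theta = theta, components = comp, per_locus = per_locus)
}

#' Permutation test for pairwise F_ST
#'
#' Individuals are shuffled between the two populations (preserving sample
#' sizes) `n_perm` times; `p = (1 + #{theta_perm >= theta_obs}) / (n_perm + 1)`.
#' Significance uses a Bonferroni-corrected level `alpha / n_tests`.
#'
#' @param x a [geno_set].
#' @param pair character vector of two population codes.
#' @param n_perm number of permutations (default 10000).
#' @param alpha nominal level (default 0.05).
#' @param n_tests number of tests for Bonferroni correction (default 1).
#' @param seed optional RNG seed.
#' @return list: `theta`, `p`, `significant`, `n_perm`.
#' @export
fst_permutation_test <- function(x, pair, n_perm = 10000, alpha = 0.05,
                                 n_tests = 1, seed = NULL) {
  stopifnot(length(pair) == 2, n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  keep <- x$samples$population %in% pair
  g <- x$geno[keep, , drop = FALSE]
  pop <- x$samples$population[keep]
  if (min(table(pop)) < 2) stop("each population needs >= 2 individuals")
  theta_of <- function(labels) {
    comp <- wc_components(g, labels)
    sum(comp["a", ], na.rm = TRUE) / sum(colSums(comp), na.rm = TRUE)
  }
  obs <- theta_of(pop)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    if (theta_of(sample(pop)) >= obs) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (n_perm + 1)
  list(theta = obs, p = p, significant = p < alpha / n_tests, n_perm = n_perm)
}

#' All pairwise F_ST with optional permutation significance
#'
#' @param x a [geno_set].
#' @param n_perm permutations per pair (0 = point estimates only).
#' @param alpha nominal level; Bonferroni-corrected by the number of pairs.
#' @param seed optional RNG seed.
#' @return list: `theta` (symmetric matrix, zero diagonal), `p` (matrix or
#'   NULL), `significant` (matrix or NULL), `n_tests`, `overall` (multi-locus
#'   theta across all populations).
#' @export
pairwise_fst <- function(x, n_perm = 0, alpha = 0.05, seed = NULL) {
  pops <- sort(unique(x$samples$population))
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations")
  n_tests <- k * (k - 1) / 2
  th <- matrix(0, k, k, dimnames = list(pops, pops))
  pm <- if (n_perm > 0) matrix(NA_real_, k, k, dimnames = list(pops, pops)) else NULL
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (n_perm > 0) {
      r <- fst_permutation_test(x, c(pops[i], pops[j]), n_perm = n_perm,
                                alpha = alpha, n_tests = n_tests)
      th[i, j] <- th[j, i] <- r$theta
      pm[i, j] <- pm[j, i] <- r$p
    } else {
      th[i, j] <- th[j, i] <- wc_fst(x, pops = c(pops[i], pops[j]))$theta
    }
  }
  sig <- if (!is.null(pm)) pm < alpha / n_tests else NULL
  list(theta = th, p = pm, significant = sig, n_tests = n_tests,
       overall = wc_fst(x)$theta)
}

#' Number of pairwise comparisons among populations
#' @param n_pops number of populations.
#' @return `choose(n_pops, 2)`.
#' @export
n_pairwise_tests <- function(n_pops) choose(n_pops, 2)

#' Linearized F_ST
#'
#' `theta / (1 - theta)`, the standard transformation for regression of
#' genetic differentiation on geographic distance. Negative input passes
#' through (slightly negative estimates are legitimate).
#'
#' @param theta F_ST estimate(s), < 1.
#' @return linearized value(s).
#' @export
linearize_fst <- function(theta) {
  if (any(theta >= 1)) stop("linearized F_ST undefined at theta >= 1")
  theta / (1 - theta)
}
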