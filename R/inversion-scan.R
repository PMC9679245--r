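#' Local PCA / MDS screen of a chromosome
#'
#' The chromosome is cut into non-overlapping windows of `window_snps` SNPs
#' (a trailing partial window is dropped). For each window the centered,
#' scaled genotype matrix is reduced to its rank-`k` approximation of the
#' individual-by-individual covariance, scaled to unit Frobenius norm; the
#' distance between two windows is the Frobenius norm of the difference of
#' those approximations. Classical (Torgerson) MDS embeds the window distance
#' matrix in up to `mds_dims` axes, and windows whose MDS1 coordinate lies
#' more than `sd_factor` standard deviations from the mean are flagged as
#' structurally atypical (putative inversion span).
#'
#' @param x a [geno_set].
#' @param chrom chromosome id.
#' @param window_snps SNPs per window (default 50).
#' @param k rank of the covariance approximation (default 2).
#' @param mds_dims maximum MDS dimensions (default 40).
#' @param sd_factor flagging threshold on MDS1 (default 3).
#' @param axes axes scanned for flagging (default 1, i.e. MDS1 only).
#' @return object of class `local_pca_map`: data.frame `windows` (`window`,
#'   `start_bp`, `end_bp`, `mds1`, `flagged`), `mds` (window x dims),
#'   `dist` (window distance matrix), `flagged_span` (bp range of flagged
#'   windows or NULL).
#' @export
local_pca_mds <- function(x, chrom, window_snps = 50, k = 2, mds_dims = 40,
                          sd_factor = 3, axes = 1) {
  idx <- which(x$snps$chrom == chrom)
  n_win <- length(idx) %/% window_snps
  if (n_win < 2) {
    return(structure(list(windows = data.frame(), mds = NULL, dist = NULL,
                          flagged_span = NULL), class = "local_pca_map"))
  }
  n <- nrow(x$geno)
  if (n < k + 1) stop("need more individuals than the approximation rank")
  # rank-k window summaries: top-k singular values/vectors of the centered
  # matrix give cov ~ U diag(d^2) U' / (n-1); scale so ||M||_F = 1
  Us <- vector("list", n_win)
  ws <- vector("list", n_win)
  starts <- ends <- integer(n_win)
  for (w in seq_len(n_win)) {
    cols <- idx[((w - 1) * window_snps + 1):(w * window_snps)]
    z <- scale_geno(x$geno[, cols, drop = FALSE])
    sv <- svd(z, nu = k, nv = 0)
    lam <- sv$d[seq_len(k)]^2
    nrm <- sqrt(sum(lam^2))
    Us[[w]] <- sv$u[, seq_len(k), drop = FALSE]
    ws[[w]] <- if (nrm > 0) lam / nrm else lam
    starts[w] <- x$snps$pos[cols[1]]
    ends[w] <- x$snps$pos[cols[length(cols)]]
  }
  # ||Ma - Mb||_F^2 = 2 - 2 * sum_{ij} wa_i wb_j (ua_i . ub_j)^2
  D <- matrix(0, n_win, n_win)
  for (a in seq_len(n_win - 1)) for (b in (a + 1):n_win) {
    cr <- crossprod(Us[[a]], Us[[b]])            # k x k
    tr <- sum((ws[[a]] %o% ws[[b]]) * cr^2)
    D[a, b] <- D[b, a] <- sqrt(max(0, 2 - 2 * tr))
  }
  dims <- min(mds_dims, n_win - 1)
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = dims))
  if (is.null(dim(mds))) mds <- matrix(mds, ncol = 1)
  if (ncol(mds) == 0) mds <- matrix(0, n_win, 1)  # all-identical windows
  flagged <- rep(FALSE, n_win)
  for (ax in axes[axes <= ncol(mds)]) {
    v <- mds[, ax]
    s <- stats::sd(v)
    if (s > 0) flagged <- flagged | abs(v - mean(v)) > sd_factor * s
  }
  windows <- data.frame(window = seq_len(n_win), start_bp = starts,
                        end_bp = ends, mds1 = mds[, 1], flagged = flagged)
  span <- if (any(flagged))
    c(start_bp = min(starts[flagged]), end_bp = max(ends[flagged])) else NULL
  structure(list(windows = windows, mds = mds, dist = D,
                 flagged_span = span), class = "local_pca_map")
}

#' @export
print.local_pca_map <- function(x, ...) {
  cat("local_pca_map:", nrow(x$windows), "windows,",
      sum(x$windows$flagged), "flagged\n")
  if (!is.null(x$flagged_span))
    cat("  flagged span:", x$flagged_span[1], "-", x$flagged_span[2], "bp\n")
  invisible(x)
}

#' Genotype clustering on region PCA
#'
#' PCA on the scaled genotypes of the region SNPs; k-means (25 seeded
#' restarts) on (PC1, PC2) for k in {2, 3}, with k chosen by mean silhouette
#' width. Clusters are interpreted as inversion genotypes: for k = 3 the two
#' PC1-extreme clusters are the homozygotes and the middle one the
#' heterozygote; for k = 2 the cluster with the higher mean observed
#' heterozygosity across region SNPs is taken as the heterozygote (`C2 = 0`,
#' the pattern expected when the minor haplotype is too rare for minor
#' homozygotes to be sampled). `C0` is always the larger homozygote cluster.
#'
#' @param x a [geno_set].
#' @param snp_ids region SNP ids (>= 2).
#' @param seed RNG seed for the k-means restarts (default 1).
#' @return object of class `genotype_clusters`: `assignments` (data.frame
#'   sample_id, population, pc1, pc2, cluster in {0,1,2}), `counts`
#'   (named C0/C1/C2), `k`, `silhouette` (named scores for k = 2, 3).
#' @export
genotype_cluster_pca <- function(x, snp_ids, seed = 1) {
  snp <- match(snp_ids, x$snps$id)
  if (anyNA(snp)) stop("unknown SNP ids")
  if (length(snp) < 2) stop("need >= 2 SNPs")
  if (nrow(x$geno) < 3) stop("need >= 3 individuals")
  g <- x$geno[, snp, drop = FALSE]
  z <- scale_geno(g)
  if (all(z == 0)) stop("degenerate PCA: region has zero variance")
  sv <- svd(z, nu = 2, nv = 0)
  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  set.seed(seed)
  km <- list()
  sil <- c(`2` = NA_real_, `3` = NA_real_)
  for (k in 2:3) {
    fit <- tryCatch(stats::kmeans(scores, centers = k, nstart = 25),
                    error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$cluster)) < k) next
    sw <- cluster::silhouette(fit$cluster, stats::dist(scores))
    sil[as.character(k)] <- mean(sw[, "sil_width"])
    km[[as.character(k)]] <- fit
  }
  if (!length(km)) stop("k-means failed for k = 2 and 3")
  k_best <- names(km)[which.max(sil[names(km)])]
  fit <- km[[k_best]]
  k <- as.integer(k_best)
  # order clusters along PC1
  ord <- order(fit$centers[, 1])
  lab_pc1 <- match(fit$cluster, ord) - 1L       # 0..k-1 along PC1
  het_rate <- vapply(seq_len(k) - 1L, function(cl) {
    rows <- lab_pc1 == cl
    mean(g[rows, , drop = FALSE] == 1L, na.rm = TRUE)
  }, numeric(1))
  sizes <- tabulate(lab_pc1 + 1L, k)
  cluster <- integer(length(lab_pc1))
  if (k == 3) {
    # ends are homozygotes; larger end = C0, middle = C1, other end = C2
    ends <- c(0L, 2L)
    major_end <- ends[which.max(sizes[ends + 1L])]
    minor_end <- setdiff(ends, major_end)
    map <- integer(3)
    map[major_end + 1L] <- 0L; map[2L] <- 1L; map[minor_end + 1L] <- 2L
    cluster <- map[lab_pc1 + 1L]
  } else {
    het_cl <- which.max(het_rate) - 1L
    hom_cl <- 1L - het_cl
    # the non-het cluster is the (major) homozygote C0; no minor homozygotes
    cluster[lab_pc1 == hom_cl] <- 0L
    cluster[lab_pc1 == het_cl] <- 1L
  }
  counts <- c(C0 = sum(cluster == 0L), C1 = sum(cluster == 1L),
              C2 = sum(cluster == 2L))
  assignments <- data.frame(sample_id = x$samples$sample_id,
                            population = x$samples$population,
                            pc1 = scores[, 1], pc2 = scores[, 2],
                            cluster = cluster, stringsAsFactors = FALSE)
  structure(list(assignments = assignments, counts = counts, k = k,
                 silhouette = sil), class = "genotype_clusters")
}

#' @export
print.genotype_clusters <- function(x, ...) {
  cat("genotype_clusters: k =", x$k, "| C0 =", x$counts["C0"],
      "C1 =", x$counts["C1"], "C2 =", x$counts["C2"], "\n")
  invisible(x)
}

#' Haplotype frequency from genotype-cluster counts
#'
#' For an inversion-like biallelic haplotype with genotype clusters C0
#' (homozygous one haplotype), C1 (heterozygous) and C2 (homozygous other
#' haplotype) among N individuals, the frequency of the haplotype homozygous
#' in C2 is `F = (2 C2 + C1) / (2N)` (and symmetrically for C0). Haplotypes
#' are named major/minor by overall frequency. Computed per population and
#' overall.
#'
#' @param clusters a `genotype_clusters` object, or a data.frame with columns
#'   `population` and `cluster` (values in 0/1/2), or a named vector
#'   c(C0=, C1=, C2=) for a single overall estimate.
#' @return data.frame with `population` ("overall" row included), `n`,
#'   `f_minor`, `f_major` (`f_minor + f_major == 1`).
#' @export
haplotype_frequency <- function(clusters) {
  if (inherits(clusters, "genotype_clusters")) {
    df <- clusters$assignments[, c("population", "cluster")]
  } else if (is.data.frame(clusters)) {
    df <- clusters[, c("population", "cluster")]
  } else {
    cn <- clusters[c("C0", "C1", "C2")]
    if (anyNA(cn)) stop("need C0, C1, C2 counts")
    df <- data.frame(
      population = "overall",
      cluster = rep(c(0L, 1L, 2L), times = cn))
  }
  if (nrow(df) == 0) stop("no individuals")
  freq_of <- function(cl) {
    n <- length(cl)
    f2 <- (2 * sum(cl == 2L) + sum(cl == 1L)) / (2 * n)  # haplotype in C2
    c(n = n, f2 = f2)
  }
  overall <- freq_of(df$cluster)
  # name haplotypes by overall frequency: minor = the rarer one
  minor_is_hap2 <- overall["f2"] <= 0.5
  rows <- lapply(split(df$cluster, df$population), freq_of)
  pops <- names(rows)
  out <- data.frame(
    population = c(pops, "overall"),
    n = c(vapply(rows, `[`, numeric(1), "n"), overall["n"]),
    f2 = c(vapply(rows, `[`, numeric(1), "f2"), overall["f2"]),
    stringsAsFactors = FALSE)
  out$f_minor <- if (minor_is_hap2) out$f2 else 1 - out$f2
  out$f_major <- 1 - out$f_minor
  out$f2 <- NULL
  rownames(out) <- NULL
  out
}

#' Export a cluster-ordered genotype heatmap matrix
#'
#' Individuals are ordered by cluster label then PC1; SNPs by position. Cell
#' codes are the dosage codes 0/1/2 with NA for missing. Written as TSV when
#' `path` is given.
#'
#' @param x a [geno_set].
#' @param snp_ids region SNP ids.
#' @param clusters a `genotype_clusters` object for the same individuals.
#' @param path optional output TSV path.
#' @return the ordered matrix (invisibly when written to `path`).
#' @export
genotype_heatmap_export <- function(x, snp_ids, clusters, path = NULL) {
  snp <- match(snp_ids, x$snps$id)
  if (anyNA(snp)) stop("unknown SNP ids")
  snp <- snp[order(x$snps$pos[snp])]
  a <- clusters$assignments
  ord <- order(a$cluster, a$pc1)
  m <- x$geno[ord, snp, drop = FALSE]
  if (!is.null(path)) {
    utils::write.table(cbind(sample_id = rownames(m), cluster = a$cluster[ord],
                             as.data.frame(m)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(m))
  }
  m
}
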