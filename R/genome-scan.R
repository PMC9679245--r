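# Center dosages by 2p and scale by sqrt(2p(1-p)); missing entries imputed
# to 0 after centering (i.e. to the SNP mean). Monomorphic SNPs come back as
# all-zero columns.
scale_geno <- function(g) {
  n <- colSums(!is.na(g))
  p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), 0)
  denom <- sqrt(2 * p * (1 - p))
  denom[denom == 0] <- 1
  z <- sweep(g, 2, 2 * p)
  z <- sweep(z, 2, denom, "/")
  z[is.na(z)] <- 0
  z
}

#' LD-aware SNP thinning for PC estimation
#'
#' Two-stage thinning in the style of iterative SVD pruning: (1) greedy
#' clumping — SNPs are visited in decreasing-MAF order and each visited SNP
#' removes all not-yet-visited SNPs within `window_snps` positions (SNP
#' ordinal, same chromosome) whose squared dosage correlation with it exceeds
#' `thin_r2`; (2) long-range-LD pruning — PCA loadings are computed on the
#' retained set and SNPs whose loading on any PC lies more than 6 MADs from
#' the per-PC median are flagged; contiguous flagged runs are dropped as
#' intervals, and the procedure repeats until no interval is flagged or
#' `max_iter` is reached. SNPs with `mac < min_mac` are excluded up front.
#'
#' @param x a [geno_set].
#' @param thin_r2 squared-correlation threshold (default 0.2).
#' @param window_snps clumping window half-width in SNP ordinals (default 50).
#' @param min_mac minimum minor allele count (default 3).
#' @param max_iter maximum pruning iterations (default 10).
#' @param k_pc number of PCs inspected for loading outliers (default 5).
#' @param mad_factor MAD multiple for the loading flag (default 6).
#' @param min_run minimum run length (in SNPs) for an interval drop
#'   (default 3; isolated flags are kept).
#' @return list: `keep` (retained SNP indices into `x$snps`), `n_iter`,
#'   `dropped_intervals` (data.frame chrom/start/end of pruned runs).
#' @export
ld_clump_thin <- function(x, thin_r2 = 0.2, window_snps = 50, min_mac = 3,
                          max_iter = 10, k_pc = 5, mad_factor = 6,
                          min_run = 3) {
  eligible <- which(x$snps$mac >= min_mac)
  if (length(eligible) < 2) stop("fewer than 2 SNPs pass min_mac")
  z <- scale_geno(x$geno[, eligible, drop = FALSE])
  zn <- sweep(z, 2, pmax(sqrt(colSums(z^2)), .Machine$double.eps), "/")
  chrom <- x$snps$chrom[eligible]
  maf <- x$snps$maf[eligible]
  m <- length(eligible)
  alive <- rep(TRUE, m)
  visited <- rep(FALSE, m)
  for (i in order(-maf)) {
    if (!alive[i] || visited[i]) next
    visited[i] <- TRUE
    lo <- max(1, i - window_snps); hi <- min(m, i + window_snps)
    nb <- lo:hi
    nb <- nb[alive[nb] & !visited[nb] & chrom[nb] == chrom[i]]
    if (length(nb)) {
      r2 <- drop(crossprod(zn[, nb, drop = FALSE], zn[, i]))^2
      alive[nb[r2 > thin_r2]] <- FALSE
    }
  }
  dropped <- data.frame(chrom = character(), start = integer(), end = integer())
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    idx <- which(alive)
    k <- min(k_pc, length(idx) - 1, nrow(z) - 1)
    sv <- svd(z[, idx, drop = FALSE], nu = 0, nv = k)
    flag <- rep(FALSE, length(idx))
    for (j in seq_len(k)) {
      v <- sv$v[, j]
      med <- stats::median(v); md <- stats::mad(v)
      if (md > 0) flag <- flag | abs(v - med) > mad_factor * md
    }
    runs <- rle(flag)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    drop_any <- FALSE
    for (q in which(runs$values & runs$lengths >= min_run)) {
      seg <- idx[starts[q]:ends[q]]
      if (length(unique(chrom[seg])) == 1) {
        alive[seg] <- FALSE
        drop_any <- TRUE
        dropped <- rbind(dropped, data.frame(
          chrom = chrom[seg[1]],
          start = x$snps$pos[eligible[seg[1]]],
          end = x$snps$pos[eligible[seg[length(seg)]]]))
      }
    }
    if (!drop_any || n_iter >= max_iter) break
  }
  list(keep = eligible[alive], n_iter = n_iter, dropped_intervals = dropped)
}

#' Choose the number of PCs from the scree curve
#'
#' Eigenvalues of the scaled genotype covariance are computed for
#' `1..k_max + 1`; the automated elbow picks the largest K whose *relative*
#' drop `(lambda_K - lambda_{K+1}) / lambda_{K+1}` exceeds both `factor`
#' times the median relative drop across the examined range and an absolute
#' floor of 0.05 (the bulk spectrum of an unstructured sample declines in
#' small, even relative steps, so genuine structure stands out as a large
#' relative gap). An explicit `override` always wins.
#'
#' @param x a [geno_set].
#' @param thin SNP indices used for PC estimation (e.g. from
#'   [ld_clump_thin]); default all SNPs.
#' @param k_max largest K examined (default 10).
#' @param factor elbow sensitivity (default 3).
#' @param override user-chosen K, returned as-is when non-NULL.
#' @return list: `K`, `eigenvalues`, `override` (logical).
#' @export
choose_k_scree <- function(x, thin = NULL, k_max = 10, factor = 3,
                           override = NULL) {
  if (!is.null(override)) {
    return(list(K = as.integer(override), eigenvalues = NULL, override = TRUE))
  }
  if (k_max < 2) stop("k_max must be >= 2")
  if (is.null(thin)) thin <- seq_len(ncol(x$geno))
  z <- scale_geno(x$geno[, thin, drop = FALSE])
  k_max <- min(k_max, nrow(z) - 1, length(thin) - 1)
  d <- svd(z, nu = 0, nv = 0)$d
  ev <- (d^2 / (nrow(z) - 1))[seq_len(k_max + 1)]
  rel <- -diff(ev) / ev[-1]             # relative drop lambda_K -> lambda_{K+1}
  thr <- max(factor * stats::median(rel), 0.05)
  K <- if (any(rel > thr)) max(which(rel > thr)) else 1L
  list(K = as.integer(K), eigenvalues = ev, override = FALSE)
}

#' PCA Mahalanobis genome scan
#'
#' The pcadapt-style outlier scan: principal components are estimated from
#' the thinned SNP set (SVD of the centered/scaled genotype matrix, missing
#' entries imputed to the SNP mean); every SNP with `maf >= min_maf` is then
#' regressed on the K individual score vectors, giving a K-vector of
#' regression z-scores per SNP; the squared robust Mahalanobis distance D2 of
#' those vectors (minimum covariance determinant estimate of center/scatter)
#' is calibrated by the genomic inflation factor
#' `lambda = median(D2) / qchisq(0.5, K)` and referred to the chi-squared(K)
#' upper tail. Outliers are SNPs with q-value (from [compute_qvalues])
#' below `q_threshold`.
#'
#' @param x a [geno_set].
#' @param thin SNP indices for PC estimation (default: all).
#' @param K number of PCs retained.
#' @param min_maf MAF floor for tested SNPs (default 0.05); SNPs below it get
#'   missing p/q and are never outliers.
#' @param q_threshold outlier q-value cutoff (default 0.01).
#' @param cov_method "mcd" (robust, default) or "classical"; MCD failure
#'   falls back to a median/MAD diagonal estimate with a warning.
#' @param scope label recorded on the result (e.g. "full", "eastern").
#' @param seed optional seed (MCD subsampling).
#' @return object of class `scan_result`: data.frame `table` (chrom, pos,
#'   maf, D2, p, q, outlier, scope) plus `z` (K x n_snp), `lambda`, `K`,
#'   `scores` (individual PC scores), `scope`.
#' @export
pcadapt_scan <- function(x, thin = NULL, K = 2, min_maf = 0.05,
                         q_threshold = 0.01, cov_method = c("mcd", "classical"),
                         scope = "full", seed = NULL) {
  cov_method <- match.arg(cov_method)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(thin)) thin <- seq_len(ncol(x$geno))
  n <- nrow(x$geno)
  if (K >= n) stop("K must be smaller than the number of individuals")
  zt <- scale_geno(x$geno[, thin, drop = FALSE])
  sv <- svd(zt, nu = K, nv = 0)
  U <- sv$u[, seq_len(K), drop = FALSE]       # orthonormal score basis
  z_all <- scale_geno(x$geno)
  B <- crossprod(U, z_all)                    # K x p regression coefficients
  rss <- pmax(colSums(z_all^2) - colSums(B^2), 0)
  sigma <- sqrt(rss / (n - K))
  zscore <- sweep(B, 2, pmax(sigma, .Machine$double.eps), "/")

  tested <- which(x$snps$maf >= min_maf)
  D2 <- rep(NA_real_, ncol(x$geno))
  zt_mat <- t(zscore[, tested, drop = FALSE])  # n_tested x K
  if (cov_method == "classical") {
    ctr <- colMeans(zt_mat)
    S <- stats::cov(zt_mat)
  } else {
    rb <- tryCatch(MASS::cov.rob(zt_mat, method = "mcd"),
                   error = function(e) NULL)
    if (is.null(rb) || inherits(try(solve(rb$cov), silent = TRUE), "try-error")) {
      warning("MCD covariance singular; falling back to median/MAD diagonal")
      ctr <- apply(zt_mat, 2, stats::median)
      S <- diag(apply(zt_mat, 2, stats::mad)^2, ncol = K)
    } else {
      # one-step reweighting: trim at the chi-squared 0.975 quantile and
      # rescale by the trimming consistency factor (standard MCD practice;
      # the raw MCD scatter is biased low)
      d_raw <- stats::mahalanobis(zt_mat, rb$center, rb$cov)
      w <- d_raw <= stats::qchisq(0.975, df = K)
      ctr <- colMeans(zt_mat[w, , drop = FALSE])
      S <- stats::cov(zt_mat[w, , drop = FALSE]) /
        (stats::pchisq(stats::qchisq(0.975, K), K + 2) / 0.975)
    }
  }
  D2[tested] <- stats::mahalanobis(zt_mat, ctr, S)
  lambda <- stats::median(D2[tested]) / stats::qchisq(0.5, df = K)
  p <- rep(NA_real_, ncol(x$geno))
  p[tested] <- stats::pchisq(D2[tested] / lambda, df = K, lower.tail = FALSE)
  p[tested] <- pmax(p[tested], .Machine$double.xmin)  # keep p in (0, 1]
  q <- rep(NA_real_, ncol(x$geno))
  q[tested] <- compute_qvalues(p[tested])
  tab <- data.frame(id = x$snps$id, chrom = x$snps$chrom, pos = x$snps$pos,
                    maf = x$snps$maf, D2 = D2, p = p, q = q,
                    outlier = !is.na(q) & q < q_threshold,
                    scope = scope, stringsAsFactors = FALSE)
  structure(list(table = tab, z = zscore, lambda = lambda, K = K,
                 scores = sv$u %*% diag(sv$d[seq_len(K)], K), scope = scope),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result (scope ", x$scope, "): K = ", x$K,
      ", lambda = ", signif(x$lambda, 4), ", ",
      sum(x$table$outlier), " outliers / ", sum(!is.na(x$table$p)),
      " tested SNPs\n", sep = "")
  invisible(x)
}

#' False-discovery-rate q-values
#'
#' Storey q-values with smoother-based pi0 estimation over the lambda grid
#' 0.05..0.95 when at least `min_storey` p-values are supplied; otherwise
#' (or when `method = "bh"`) Benjamini-Hochberg, i.e. Storey with pi0 = 1.
#' Missing p-values propagate to missing q-values.
#'
#' @param p vector of p-values in (0, 1] (NA allowed).
#' @param method "auto" (default), "storey" or "bh".
#' @param min_storey minimum number of tests for the Storey estimator under
#'   "auto" (default 100).
#' @return q-values, same length/order as `p`.
#' @export
compute_qvalues <- function(p, method = c("auto", "storey", "bh"),
                            min_storey = 100) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (!any(ok)) stop("all p-values missing")
  pv <- p[ok]
  if (any(pv <= 0 | pv > 1)) stop("p-values must lie in (0, 1]")
  m <- length(pv)
  use_storey <- method == "storey" || (method == "auto" && m >= min_storey)
  pi0 <- 1
  if (use_storey) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- min(max(stats::predict(fit, x = max(lam))$y, 0), 1)
    if (pi0 <= 0) pi0 <- 1  # degenerate estimate: fall back to BH
  }
  o <- order(pv)
  q_sorted <- pi0 * m * pv[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}

#' Union of outlier sets across scan scopes
#'
#' SNPs flagged in any of the supplied scans are combined, with the list of
#' contributing scopes retained per SNP. All scans must share a SNP universe.
#'
#' @param results list of `scan_result` objects.
#' @return data.frame: `id`, `chrom`, `pos`, `scopes` (comma-separated).
#' @export
combine_outlier_sets <- function(results) {
  ids <- lapply(results, function(r) r$table$id)
  if (length(unique(vapply(ids, paste, character(1), collapse = "\r"))) != 1)
    stop("scan results do not share a SNP universe")
  tab <- results[[1]]$table[, c("id", "chrom", "pos")]
  hits <- lapply(results, function(r) r$table$outlier)
  any_hit <- Reduce(`|`, hits)
  scopes <- vapply(seq_len(nrow(tab)), function(i) {
    paste(vapply(results[sapply(hits, `[`, i)], function(r) r$scope,
                 character(1)), collapse = ",")
  }, character(1))
  out <- tab[any_hit, , drop = FALSE]
  out$scopes <- scopes[any_hit]
  rownames(out) <- NULL
  out
}
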