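#' Binary land/water resistance raster
#'
#' A grid in which water cells have resistance 1 and land cells infinite
#' resistance, used to compute in-water least-cost distances. Cell (1,1) is
#' the upper-left corner; x increases with column, y increases downward with
#' row (plain matrix convention). Coordinates are in cell-size units with the
#' center of cell (r, c) at `x = (c - 0.5) * cellsize`,
#' `y = (r - 0.5) * cellsize`.
#'
#' @param water logical matrix, `TRUE` = water.
#' @param cellsize side length of a cell (arbitrary units, default 1).
#' @return object of class `resistance_raster`.
#' @export
resistance_raster <- function(water, cellsize = 1) {
  water <- as.matrix(water)
  if (!is.logical(water)) stop("water must be a logical matrix")
  if (length(water) == 0) stop("empty raster")
  structure(list(water = water, cellsize = cellsize), class = "resistance_raster")
}

#' @export
print.resistance_raster <- function(x, ...) {
  cat("resistance_raster:", nrow(x$water), "x", ncol(x$water),
      "cells,", sum(x$water), "water, cellsize", x$cellsize, "\n")
  invisible(x)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Land is encoded as the NODATA value, water as 1.
#' @param x a `resistance_raster`.
#' @param path file path.
#' @return `path` invisibly (write); a `resistance_raster` (read).
#' @export
write_ascii_grid <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(x$water)), paste("nrows", nrow(x$water)),
               "xllcorner 0", "yllcorner 0",
               paste("cellsize", x$cellsize), "NODATA_value -9999"), con)
  m <- ifelse(x$water, 1, -9999)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  resistance_raster(m != vals[["nodata_value"]], cellsize = vals[["cellsize"]])
}

# Snap (x, y) coordinates to the nearest water cell within `tol` cell-sizes.
snap_to_water <- function(raster, coords, tol = 3) {
  w <- raster$water
  cs <- raster$cellsize
  wc <- which(w, arr.ind = TRUE)
  wx <- (wc[, 2] - 0.5) * cs
  wy <- (wc[, 1] - 0.5) * cs
  idx <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    d2 <- (wx - coords$x[i])^2 + (wy - coords$y[i])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > tol * cs)
      stop("population ", coords$pop[i], " is on land beyond the snap tolerance")
    idx[i] <- (wc[j, 2] - 1) * nrow(w) + wc[j, 1]  # linear cell index
  }
  idx
}

#' In-water least-cost distances between populations
#'
#' Builds a lattice graph over water cells (4-, 8- or 16-neighbor
#' connectivity) with edge weight = cellsize x step length (1 for rook moves,
#' sqrt(2) for diagonals, sqrt(5) for knight moves) x mean resistance of the
#' two cells (1 for water), and runs Dijkstra shortest paths between the
#' population cells. Populations are snapped to the nearest water cell within
#' `tol` cell-sizes.
#'
#' @param raster a [resistance_raster].
#' @param coords data.frame `pop`, `x`, `y` in raster units.
#' @param directions 4, 8 (default) or 16.
#' @param tol snap tolerance in cell-sizes (default 3).
#' @return symmetric distance matrix (populations x populations).
#' @export
least_cost_distances <- function(raster, coords, directions = 8, tol = 3) {
  stopifnot(directions %in% c(4, 8, 16))
  w <- raster$water
  nr <- nrow(w); ncl <- ncol(w)
  cs <- raster$cellsize
  steps <- list(c(1, 0, 1), c(0, 1, 1))                    # (dr, dc, length)
  if (directions >= 8) steps <- c(steps, list(c(1, 1, sqrt(2)), c(1, -1, sqrt(2))))
  if (directions == 16)
    steps <- c(steps, list(c(1, 2, sqrt(5)), c(2, 1, sqrt(5)),
                           c(1, -2, sqrt(5)), c(2, -1, sqrt(5))))
  cell <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  rr <- row(w); cc <- col(w)
  for (s in steps) {
    r2 <- rr + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncl & w
    ok[ok] <- w[cbind(r2[ok], c2[ok])]
    from <- c(from, cell(rr[ok], cc[ok]))
    to <- c(to, cell(r2[ok], c2[ok]))
    wt <- c(wt, rep(cs * s[3], sum(ok)))
  }
  gr <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  gr <- igraph::set_edge_attr(gr, "weight", value = wt)
  # isolated water cells may be absent from the edge list; pad vertex set
  if (igraph::vcount(gr) < nr * ncl)
    gr <- igraph::add_vertices(gr, nr * ncl - igraph::vcount(gr))
  nodes <- snap_to_water(raster, coords, tol = tol)
  d <- igraph::distances(gr, v = nodes, to = nodes, algorithm = "dijkstra")
  dimnames(d) <- list(coords$pop, coords$pop)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop("populations ", coords$pop[bad[1]], " and ", coords$pop[bad[2]],
         " are not connected by water")
  }
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles; the null distribution is built
#' by simultaneously permuting rows and columns of `d2`. One-sided
#' (upper-tail) p with the +1 correction.
#'
#' @param d1,d2 conformable symmetric matrices.
#' @param n_perm permutations (default 10000).
#' @param seed optional RNG seed.
#' @return list: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 3) stop("Mantel test needs at least 3 populations")
  stopifnot(identical(dim(d1), dim(d2)))
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(d1)
  r_obs <- stats::cor(d1[lt], d2[lt])
  if (is.na(r_obs)) stop("degenerate distance matrix (zero variance)")
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    pp <- sample.int(n)
    if (stats::cor(d1[lt], d2[pp, pp][lt]) >= r_obs) exceed <- exceed + 1L
  }
  list(r = r_obs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of linearized F_ST, `theta / (1 - theta)`, on
#' pairwise in-water distance, plus a Mantel test on the same pair set.
#' Populations named in `exclude` are removed from both matrices first.
#'
#' @param fst symmetric matrix of pairwise F_ST (theta).
#' @param dist symmetric distance matrix with the same population order.
#' @param exclude character vector of populations to drop (default none).
#' @param n_perm Mantel permutations.
#' @param seed optional RNG seed.
#' @return list: `slope`, `intercept`, `mantel` (list r/p/n_perm), `pairs`
#'   (data.frame of the regression points).
#' @export
ibd_regression <- function(fst, dist, exclude = character(), n_perm = 10000,
                           seed = NULL) {
  stopifnot(identical(rownames(fst), rownames(dist)))
  keep <- !(rownames(fst) %in% exclude)
  if (sum(keep) < 3) stop("fewer than 3 populations after exclusion")
  f <- fst[keep, keep]; d <- dist[keep, keep]
  lt <- lower.tri(f)
  y <- linearize_fst(f[lt]); xv <- d[lt]
  if (stats::sd(xv) == 0) stop("degenerate predictor: all distances equal")
  fit <- stats::lm(y ~ xv)
  lin <- f / (1 - f)
  mt <- mantel_test(lin, d, n_perm = n_perm, seed = seed)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), mantel = mt,
       pairs = data.frame(distance = xv, linearized_fst = y))
}
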