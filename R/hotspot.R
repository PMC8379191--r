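#' Discretise centroids onto a counting grid
#'
#' Cells are half-open squares `[k*s, (k+1)*s)` in 0-based pixel
#' coordinates (a centroid at exactly `(s, s)` falls in cell (1, 1) of
#' the 0-based grid). The ragged final row/column is kept and its cell
#' centres adjusted to the truncated extent. The total count equals
#' the number of centroids of the requested phenotype.
#'
#' @param centroids data.frame with `x_px`, `y_px` and optionally a
#'   `phenotype` column.
#' @param fieldDimPx numeric(2), field (width, height) in pixels.
#' @param cellSizePx grid cell size in pixels, >= 1.
#' @param phenotype optional phenotype filter (requires the column).
#' @return a [GridCounts-class].
#' @export
gridDiscretise <- function(centroids, fieldDimPx, cellSizePx,
                           phenotype = NULL) {
  if (cellSizePx < 1) stop("cellSizePx must be >= 1")
  w <- fieldDimPx[1L]; h <- fieldDimPx[2L]
  if (!is.null(phenotype)) {
    centroids <- centroids[centroids$phenotype == phenotype, , drop = FALSE]
  } else phenotype <- "all"
  nc <- max(1L, ceiling(w / cellSizePx))
  nr <- max(1L, ceiling(h / cellSizePx))
  counts <- matrix(0L, nr, nc)
  if (nrow(centroids)) {
    if (any(centroids$x_px < 0 | centroids$x_px >= w |
            centroids$y_px < 0 | centroids$y_px >= h))
      stop("centroids must lie within the field")
    ci <- pmin(nc - 1L, floor(centroids$x_px / cellSizePx)) + 1L
    ri <- pmin(nr - 1L, floor(centroids$y_px / cellSizePx)) + 1L
    tab <- table(factor(ri, levels = seq_len(nr)),
                 factor(ci, levels = seq_len(nc)))
    counts <- matrix(as.integer(tab), nr, nc)
  } else {
    warning("no centroids of phenotype '", phenotype,
            "'; returning an all-zero grid")
  }
  new("GridCounts", counts = counts, cellSizePx = cellSizePx,
      fieldDimPx = as.numeric(fieldDimPx), phenotype = phenotype)
}

## Binary neighbour weights between grid-cell centres: w_ij = 1 iff
## 0 < d_ij < d (strict, self excluded). Returns a list of neighbour
## index vectors; exact also for ragged edge cells. Candidates are
## restricted to the axis-aligned d-window around each cell, so the
## scan is O(n * window) rather than O(n^2).
gridNeighbourList <- function(grid, dPx) {
  ctr <- gridCellCentres(grid)
  nr <- nrow(grid@counts); nc <- ncol(grid@counts)
  n <- nr * nc
  nbr <- vector("list", n)
  d2 <- dPx^2
  for (ci in seq_len(nc)) {
    cols <- which(abs(ctr$x - ctr$x[ci]) < dPx)
    dxc <- ctr$x[cols] - ctr$x[ci]
    for (ri in seq_len(nr)) {
      rows <- which(abs(ctr$y - ctr$y[ri]) < dPx)
      dyr <- ctr$y[rows] - ctr$y[ri]
      dd <- outer(dyr^2, dxc^2, "+")
      hit <- which(dd < d2)
      ## linear indices (column-major) of candidate block
      lin <- rep((cols - 1L) * nr, each = length(rows)) + rows
      i <- (ci - 1L) * nr + ri
      hits <- lin[hit]
      nbr[[i]] <- hits[hits != i]
    }
  }
  nbr
}

#' Getis-Ord GI*(d) on a counting grid
#'
#' For each grid cell `i` (self excluded, `w_ii = 0`):
#' `G_i = sum_{j != i} w_ij x_j / sum_{j != i} x_j` with binary weights
#' `w_ij = 1` iff the Euclidean distance between cell centres is
#' strictly less than `d`. Under conditional randomisation the
#' expectation is `E = W_i / (n - 1)` and the variance follows the
#' Getis-Ord randomisation moments
#' `Var = W_i (n - 1 - W_i) / ((n - 1)^2 (n - 2)) * (Y_2 / Y_1^2)` with
#' `Y_1 = sum_{j != i} x_j / (n - 1)` and
#' `Y_2 = sum_{j != i} x_j^2 / (n - 1) - Y_1^2`; `Z = (G - E)/sqrt(Var)`.
#' Degenerate cells (`Var = 0`) take `Z = 0`; cells whose excluded sum
#' is zero are flagged undefined. Edge cells keep their truncated
#' neighbourhoods.
#'
#' @param grid a [GridCounts-class].
#' @param dPx neighbourhood scale d in pixels (strict upper bound).
#' @return a [GetisOrdResult-class].
#' @export
getisOrd <- function(grid, dPx) {
  x <- as.numeric(grid@counts)
  n <- length(x)
  if (n < 3L) stop("the statistic needs at least 3 grid cells")
  if (sum(x) == 0) stop("all grid counts are zero")
  nbr <- gridNeighbourList(grid, dPx)
  S <- sum(x); S2 <- sum(x^2)
  W <- vapply(nbr, length, integer(1L))
  num <- vapply(nbr, function(j) sum(x[j]), numeric(1L))
  exSum <- S - x
  defined <- exSum > 0
  G <- ifelse(defined, num / exSum, NA_real_)
  E <- W / (n - 1)
  Y1 <- exSum / (n - 1)
  Y2 <- (S2 - x^2) / (n - 1) - Y1^2
  Var <- W * (n - 1 - W) / ((n - 1)^2 * (n - 2)) * (Y2 / Y1^2)
  Var[!defined] <- NA_real_
  Var <- pmax(Var, 0)
  Z <- ifelse(defined & Var > 0, (G - E) / sqrt(Var),
              ifelse(defined, 0, NA_real_))

  nr <- nrow(grid@counts); nc <- ncol(grid@counts)
  ctr <- gridCellCentres(grid)
  stats <- data.frame(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x_px = rep(ctr$x, each = nr),
    y_px = rep(ctr$y, times = nc),
    count = as.integer(x), W = W, G = G, E = E, Var = Var, Z = Z,
    defined = defined)
  new("GetisOrdResult", stats = stats, gridDim = c(nr, nc),
      cellSizePx = grid@cellSizePx, dPx = dPx, nPerm = 0L)
}

#' Conditional permutation null for GI*(d)
#'
#' For each cell `i` the observed value `x_i` is held fixed and the
#' remaining values are permuted over the remaining cells; the
#' empirical mean, variance, z-score and upper-tail p-value of `G_i`
#' are returned. `exhaustive = TRUE` enumerates all
#' `choose(n - 1, W_i)` neighbour subsets instead (exact moments;
#' feasible for small grids only).
#'
#' @param grid a [GridCounts-class].
#' @param dPx neighbourhood scale in pixels.
#' @param nPerm number of permutations (at least 1; 99 or more
#'   recommended).
#' @param seed RNG seed.
#' @param exhaustive enumerate instead of sampling.
#' @return a [GetisOrdResult-class] whose stats carry `permMean`,
#'   `permVar`, `permZ` and `permP` columns.
#' @export
permutationNull <- function(grid, dPx, nPerm = 999L, seed = 1L,
                            exhaustive = FALSE) {
  res <- getisOrd(grid, dPx)
  x <- as.numeric(grid@counts)
  n <- length(x)
  nbr <- gridNeighbourList(grid, dPx)
  st <- res@stats
  if (exhaustive) {
    pm <- matrix(NA_real_, n, 4L)
    for (i in seq_len(n)) {
      others <- x[-i]
      k <- length(nbr[[i]])
      denom <- sum(others)
      if (denom == 0) next
      if (k == 0L) { pm[i, ] <- c(0, 0, NA, 1); next }
      sums <- combn(others, k, sum)
      Gs <- sums / denom
      mu <- mean(Gs); vv <- mean((Gs - mu)^2)
      z <- if (vv > 0) (st$G[i] - mu) / sqrt(vv) else 0
      pm[i, ] <- c(mu, vv, z, mean(Gs >= st$G[i] - 1e-12))
    }
  } else {
    if (nPerm < 1L) stop("nPerm must be at least 1")
    pm <- withSeed(seed,
                   permNullCpp(x, lapply(nbr, as.integer), as.integer(nPerm)))
  }
  st$permMean <- pm[, 1L]; st$permVar <- pm[, 2L]
  st$permZ <- pm[, 3L]; st$permP <- pm[, 4L]
  res@stats <- st
  res@nPerm <- if (exhaustive) -1L else as.integer(nPerm)
  res
}

#' Threshold a Getis-Ord result into a hotspot mask
#'
#' A grid cell is flagged iff its z-score is at least `zThreshold`
#' (one-sided, high); undefined cells are never flagged.
#'
#' @param result a [GetisOrdResult-class].
#' @param zThreshold default 1.96.
#' @return logical matrix over the grid.
#' @export
hotspotMask <- function(result, zThreshold = 1.96) {
  m <- matrix(FALSE, result@gridDim[1L], result@gridDim[2L])
  st <- result@stats
  flag <- st$defined & !is.na(st$Z) & st$Z >= zThreshold
  m[cbind(st$row, st$col)] <- flag
  m
}

#' Axis coordinate of grid cells relative to lobule geometry
#'
#' Maps each grid-cell centre to the normalised growth-axis coordinate
#' `u` of the nearest lobule (0 = trailing, 1 = leading edge).
#'
#' @param grid a [GridCounts-class] (or a [GetisOrdResult-class]).
#' @param lobules data.frame as stored in [GroundTruth-class].
#' @return matrix of `u` values over the grid.
#' @export
gridAxisCoord <- function(grid, lobules) {
  if (is(grid, "GetisOrdResult")) {
    nr <- grid@gridDim[1L]; nc <- grid@gridDim[2L]
    cx <- grid@stats$x_px; cy <- grid@stats$y_px
  } else {
    ctr <- gridCellCentres(grid)
    nr <- nrow(grid@counts); nc <- ncol(grid@counts)
    cx <- rep(ctr$x, each = nr); cy <- rep(ctr$y, times = nc)
  }
  if (!nrow(lobules)) return(matrix(NA_real_, nr, nc))
  uBest <- rep(NA_real_, length(cx)); dBest <- rep(Inf, length(cx))
  for (k in seq_len(nrow(lobules))) {
    lb <- lobules[k, ]
    dx <- cx - lb$cx; dy <- cy - lb$cy
    d2 <- dx^2 + dy^2
    upd <- d2 < dBest
    proj <- dx * lb$axisX + dy * lb$axisY
    u <- pmin(1, pmax(0, (proj + lb$a) / (2 * lb$a)))
    uBest[upd] <- u[upd]; dBest[upd] <- d2[upd]
  }
  matrix(uBest, nr, nc)
}

#' Polarisation index of a hotspot mask
#'
#' Fraction of flagged grid cells whose axis coordinate exceeds 0.5;
#' 0.5 under no polarisation, 1 when all hotspots sit on the leading
#' half. `NA` (with a warning) when no cell is flagged.
#'
#' @param mask logical hotspot grid from [hotspotMask()].
#' @param axisU matrix of axis coordinates from [gridAxisCoord()].
#' @return list with `index`, `nHotspot`, `nLeading`.
#' @export
polarisationIndex <- function(mask, axisU) {
  u <- axisU[mask]
  u <- u[!is.na(u)]
  if (!length(u)) {
    warning("empty hotspot set; polarisation index undefined")
    return(list(index = NA_real_, nHotspot = 0L, nLeading = 0L))
  }
  list(index = mean(u > 0.5), nHotspot = length(u),
       nLeading = sum(u > 0.5))
}
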