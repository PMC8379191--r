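#' Epithelial Ki67 pixel-area ratio
#'
#' The ratio of Ki67+ to Ki67- nucleus pixel area within the
#' epithelium mask: the epithelium mask gates both nuclei label maps
#' pixel-wise and the ratio of the surviving pixel counts is returned.
#'
#' @param masks a [MaskSet-class] with epithelium and nuclei maps.
#' @return list with `ratio`, `posPx`, `negPx` and a `defined` flag
#'   (`FALSE`, with `ratio = NA`, when no Ki67- epithelial pixel
#'   exists).
#' @export
ki67EpithelialRatio <- function(masks) {
  posPx <- sum(masks@ki67Pos > 0L & masks@epithelium)
  negPx <- sum(masks@ki67Neg > 0L & masks@epithelium)
  if (negPx == 0L) {
    warning("no Ki67- epithelial pixels; ratio undefined")
    return(list(ratio = NA_real_, posPx = posPx, negPx = 0L,
                defined = FALSE))
  }
  list(ratio = posPx / negPx, posPx = posPx, negPx = negPx,
       defined = TRUE)
}

#' Arc-length projection of points onto a polyline
#'
#' @param x,y point coordinates (px).
#' @param polyline data.frame with `x_px`, `y_px` (vertices in order).
#' @param pixelSizeUm micrometres per pixel.
#' @return arc-length positions (um) of the closest points on the
#'   polyline.
#' @export
projectOntoPolyline <- function(x, y, polyline, pixelSizeUm = 1) {
  vx <- diff(polyline$x_px); vy <- diff(polyline$y_px)
  segLen <- sqrt(vx^2 + vy^2)
  s0 <- c(0, cumsum(segLen))
  out <- numeric(length(x))
  for (p in seq_along(x)) {
    best <- Inf; bestS <- 0
    for (k in seq_along(vx)) {
      if (segLen[k] == 0) next
      tt <- ((x[p] - polyline$x_px[k]) * vx[k] +
               (y[p] - polyline$y_px[k]) * vy[k]) / segLen[k]^2
      tt <- min(1, max(0, tt))
      ex <- polyline$x_px[k] + tt * vx[k] - x[p]
      ey <- polyline$y_px[k] + tt * vy[k] - y[p]
      d2 <- ex^2 + ey^2
      if (d2 < best) { best <- d2; bestS <- s0[k] + tt * segLen[k] }
    }
    out[p] <- bestS
  }
  out * pixelSizeUm
}

#' Detect periodic runs of intraepithelial macrophages
#'
#' A run is a maximal stretch of at least `minLen` consecutive
#' positions whose successive arc-length gaps have a coefficient of
#' variation at most `cvTol`. Tight pairs (gap below `clusterGapUm`)
#' are first merged to their centroid, so a doublet inside an
#' otherwise periodic segment does not break it; tight groups of three
#' or more are left untouched (and typically break the run, excluding
#' them).
#'
#' @param positionsUm sorted arc-length positions (um) along one duct.
#' @param cvTol gap coefficient-of-variation tolerance.
#' @param minLen minimum run length in positions.
#' @param clusterGapUm pair-merge threshold.
#' @return list of runs, each `list(positions, gaps)`.
#' @export
detectPeriodicRuns <- function(positionsUm, cvTol = 0.30, minLen = 4L,
                               clusterGapUm = 8) {
  pos <- sort(positionsUm)
  if (length(pos) < 2L) return(list())
  ## merge isolated tight pairs
  merged <- numeric(0)
  i <- 1L
  while (i <= length(pos)) {
    if (i < length(pos) && (pos[i + 1L] - pos[i]) < clusterGapUm) {
      ## size of the tight group starting here
      j <- i
      while (j < length(pos) && (pos[j + 1L] - pos[j]) < clusterGapUm)
        j <- j + 1L
      if (j - i + 1L == 2L) {
        merged <- c(merged, mean(pos[i:j]))
      } else {
        merged <- c(merged, pos[i:j])
      }
      i <- j + 1L
    } else {
      merged <- c(merged, pos[i])
      i <- i + 1L
    }
  }
  pos <- merged
  if (length(pos) < minLen) return(list())
  gaps <- diff(pos)
  cvOf <- function(g) if (length(g) < 2L) 0 else sd(g) / mean(g)
  runs <- list()
  i <- 1L
  while (i <= length(gaps)) {
    j <- i
    while (j < length(gaps) && cvOf(gaps[i:(j + 1L)]) <= cvTol)
      j <- j + 1L
    if (cvOf(gaps[i:j]) <= cvTol && (j - i + 2L) >= minLen) {
      runs[[length(runs) + 1L]] <- list(positions = pos[i:(j + 1L)],
                                        gaps = gaps[i:j])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

#' Pool inter-macrophage arc-length distances from periodic runs
#'
#' Successive arc-length differences along the duct (distances parallel
#' to the epithelium, not chords), pooled over runs.
#'
#' @param runs list from [detectPeriodicRuns()].
#' @return numeric vector of distances (um).
#' @export
interMacrophageDistances <- function(runs) {
  if (!length(runs)) return(numeric())
  unlist(lapply(runs, `[[`, "gaps"), use.names = FALSE)
}

#' Measure macrophage spacing over a whole ground-truth field
#'
#' Runs [detectPeriodicRuns()] on every duct trace of a field and
#' pools the inter-macrophage distances.
#'
#' @param gt a [GroundTruth-class].
#' @param cvTol,minLen,clusterGapUm passed to [detectPeriodicRuns()].
#' @return numeric vector of pooled distances (um).
#' @export
fieldMacrophageDistances <- function(gt, cvTol = 0.30, minLen = 4L,
                                     clusterGapUm = 8) {
  unlist(lapply(gt@ductTraces, function(d) {
    interMacrophageDistances(
      detectPeriodicRuns(d$macArcUm, cvTol, minLen, clusterGapUm))
  }), use.names = FALSE)
}

## ---- count boxes -----------------------------------------------------

#' Place stereological count boxes blind to staining
#'
#' Samples axis-aligned 400 x 230 um boxes uniformly at random among
#' positions that lie fully inside the field and whose region
#' intersects the low-resolution structure (parenchyma) mask; boxes
#' overlapping the optional artefact mask are rejected and resampled.
#' Only the structure mask is consulted, mirroring placement at a
#' magnification where staining is not discernible.
#'
#' @param structureMask logical parenchyma mask.
#' @param pixelSizeUm micrometres per pixel.
#' @param nBoxes number of boxes to place.
#' @param boxWidthUm,boxHeightUm box dimensions (um).
#' @param seed RNG seed.
#' @param artefactMask optional logical mask of excluded regions.
#' @param maxTries rejection-sampling budget per box.
#' @return data.frame of boxes: `boxId`, `x0_px`, `y0_px`, `w_px`,
#'   `h_px` (origin = top-left, 0-based).
#' @export
placeCountBoxes <- function(structureMask, pixelSizeUm, nBoxes = 8L,
                            boxWidthUm = 400, boxHeightUm = 230,
                            seed = 1L, artefactMask = NULL,
                            maxTries = 2000L) {
  if (!any(structureMask)) stop("structure mask is empty; no parenchyma to sample")
  h <- nrow(structureMask); w <- ncol(structureMask)
  bw <- boxWidthUm / pixelSizeUm; bh <- boxHeightUm / pixelSizeUm
  if (bw > w || bh > h)
    stop("count box does not fit inside the field")
  boxes <- data.frame()
  withSeed(seed, {
    placed <- 0L; tries <- 0L
    while (placed < nBoxes && tries < maxTries * nBoxes) {
      tries <- tries + 1L
      x0 <- runif(1, 0, w - bw)
      y0 <- runif(1, 0, h - bh)
      ri <- (floor(y0) + 1L):min(h, ceiling(y0 + bh))
      ci <- (floor(x0) + 1L):min(w, ceiling(x0 + bw))
      if (!any(structureMask[ri, ci])) next
      if (!is.null(artefactMask) && any(artefactMask[ri, ci])) next
      placed <- placed + 1L
      boxes <- rbind(boxes, data.frame(boxId = placed, x0_px = x0,
                                       y0_px = y0, w_px = bw, h_px = bh))
    }
    if (placed < nBoxes)
      stop("fewer valid box positions than requested (placed ", placed,
           " of ", nBoxes, ")")
  })
  boxes
}

#' Classify a count box as central or peripheral
#'
#' Peripheral iff the box intersects the parenchyma/fat-pad boundary
#' (contains both parenchyma and fat pixels) or at least `fatFrac` of
#' an annulus of width `annulusUm` around the box is fat pad;
#' otherwise central. A box with no parenchyma pixel at all is `"n/a"`.
#'
#' @param box single-row data.frame as from [placeCountBoxes()].
#' @param parenchymaMask logical mask (lobular epithelial units plus
#'   their intralobular stroma).
#' @param pixelSizeUm micrometres per pixel.
#' @param annulusUm annulus width, default 200 um.
#' @param fatFrac fat fraction threshold, default 0.2.
#' @return `"central"`, `"peripheral"` or `"n/a"`.
#' @export
classifyBoxLocation <- function(box, parenchymaMask, pixelSizeUm,
                                annulusUm = 200, fatFrac = 0.2) {
  h <- nrow(parenchymaMask); w <- ncol(parenchymaMask)
  ri <- max(1L, floor(box$y0_px) + 1L):min(h, ceiling(box$y0_px + box$h_px))
  ci <- max(1L, floor(box$x0_px) + 1L):min(w, ceiling(box$x0_px + box$w_px))
  inside <- parenchymaMask[ri, ci]
  if (!any(inside)) return("n/a")
  if (any(!inside)) return("peripheral")
  aPx <- round(annulusUm / pixelSizeUm)
  ro <- max(1L, min(ri) - aPx):min(h, max(ri) + aPx)
  co <- max(1L, min(ci) - aPx):min(w, max(ci) + aPx)
  ann <- matrix(TRUE, length(ro), length(co))
  ann[ro %in% ri, co %in% ci] <- FALSE
  fat <- !parenchymaMask[ro, co] & ann
  if (sum(fat) / sum(ann) >= fatFrac) "peripheral" else "central"
}

## fraction of a disc (centre cx,cy radius r) inside the axis-aligned
## rectangle [x0,x1]x[y0,y1], via a symmetric 720-gon clipped with
## Sutherland-Hodgman. Vertices are placed symmetrically about both
## axes so a disc bisected by an edge yields exactly one half.
discInsideFraction <- function(cx, cy, r, x0, y0, x1, y1, nVert = 720L) {
  th <- (seq_len(nVert) - 0.5) * 2 * pi / nVert
  px <- cx + r * cos(th); py <- cy + r * sin(th)
  area0 <- polyArea(px, py)
  clips <- list(c(1, 0, x0), c(-1, 0, -x1), c(0, 1, y0), c(0, -1, -y1))
  for (cl in clips) {
    if (!length(px)) break
    keep <- cl[1L] * px + cl[2L] * py >= cl[3L]
    if (all(keep)) next
    nx <- numeric(0); ny <- numeric(0)
    n <- length(px)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      a <- keep[k]; b <- keep[k2]
      if (a) { nx <- c(nx, px[k]); ny <- c(ny, py[k]) }
      if (xor(a, b)) {
        f1 <- cl[1L] * px[k] + cl[2L] * py[k] - cl[3L]
        f2 <- cl[1L] * px[k2] + cl[2L] * py[k2] - cl[3L]
        tt <- f1 / (f1 - f2)
        nx <- c(nx, px[k] + tt * (px[k2] - px[k]))
        ny <- c(ny, py[k] + tt * (py[k2] - py[k]))
      }
    }
    px <- nx; py <- ny
  }
  if (length(px) < 3L) return(0)
  polyArea(px, py) / area0
}

polyArea <- function(px, py) {
  n <- length(px)
  k2 <- c(2:n, 1L)
  abs(sum(px * py[k2] - px[k2] * py)) / 2
}

#' Count cells falling in a count box
#'
#' A cell is counted iff more than half of its nucleus footprint lies
#' inside the box; an equivocal cell (inside fraction exactly one
#' half) is counted iff its nucleus intersects the top or right box
#' edge (the standard stereological edge rule). Footprints are discs
#' of the recorded area centred on the centroid; records without an
#' area fall back to the centroid-in-box rule (half-open on the
#' bottom/left convention is then irrelevant: a point is in or out).
#'
#' @param box single-row data.frame (`x0_px`, `y0_px`, `w_px`, `h_px`).
#' @param cells data.frame with `x_px`, `y_px` and optionally
#'   `area_px`.
#' @return logical vector: counted or not, per row of `cells`.
#' @export
countCellsInBox <- function(box, cells) {
  if (!nrow(cells)) return(logical())
  x0 <- box$x0_px; y0 <- box$y0_px
  x1 <- x0 + box$w_px; y1 <- y0 + box$h_px
  hasFoot <- "area_px" %in% names(cells) && all(is.finite(cells$area_px))
  if (!hasFoot)
    return(cells$x_px >= x0 & cells$x_px < x1 &
             cells$y_px >= y0 & cells$y_px < y1)
  out <- logical(nrow(cells))
  r <- sqrt(cells$area_px / pi)
  ## quick outer reject
  maybe <- cells$x_px > x0 - r & cells$x_px < x1 + r &
    cells$y_px > y0 - r & cells$y_px < y1 + r
  for (k in which(maybe)) {
    fr <- discInsideFraction(cells$x_px[k], cells$y_px[k], r[k],
                             x0, y0, x1, y1)
    if (fr > 0.5 + 1e-9) {
      out[k] <- TRUE
    } else if (abs(fr - 0.5) <= 1e-9) {
      ## equivocal: counted on the top or right edge. The origin is
      ## top-left, so the top edge is y = y0.
      touchTop <- abs(cells$y_px[k] - y0) < r[k] &
        cells$x_px[k] > x0 - r[k] & cells$x_px[k] < x1 + r[k]
      touchRight <- abs(cells$x_px[k] - x1) < r[k] &
        cells$y_px[k] > y0 - r[k] & cells$y_px[k] < y1 + r[k]
      out[k] <- touchTop || touchRight
    }
  }
  out
}

#' Filter candidate macrophage objects by marker area
#'
#' Keeps objects whose stained area is at least half the mean luminal
#' epithelial nucleus area of the same count box (smaller fragments
#' are not counted as macrophages).
#'
#' @param areas numeric object areas.
#' @param meanLuminalArea mean luminal nucleus area in the box, or
#'   `NA`/`NaN` when the box has no luminal nuclei (then the filter is
#'   skipped with a warning).
#' @return logical keep vector.
#' @export
filterMacrophageObjects <- function(areas, meanLuminalArea) {
  if (!length(areas)) return(logical())
  if (!is.finite(meanLuminalArea)) {
    warning("no luminal nuclei in box; macrophage size filter skipped")
    return(rep(TRUE, length(areas)))
  }
  areas >= 0.5 * meanLuminalArea
}

#' Immune cell densities for one measured count box
#'
#' Normalisations: stromal macrophages per mm^2 of intralobular
#' stromal area; epithelial T lymphocytes per 100 luminal epithelial
#' nuclei; stromal T lymphocytes per mm^2 of total stromal area.
#' Records whose normaliser is zero are flagged undefined.
#'
#' @param counts named list/vector with `stromalMac`, `epithelialT`,
#'   `stromalT`, `luminalNuclei`.
#' @param intralobularStromaMm2,totalStromaMm2 stromal areas (mm^2).
#' @return data.frame with `measure`, `value`, `units`, `defined`.
#' @export
immuneDensities <- function(counts, intralobularStromaMm2,
                            totalStromaMm2) {
  rec <- function(measure, num, den, scale, units) {
    ok <- is.finite(den) && den > 0
    data.frame(measure = measure,
               value = if (ok) num / den * scale else NA_real_,
               units = units, defined = ok)
  }
  rbind(
    rec("stromal_macrophage_density", counts$stromalMac,
        intralobularStromaMm2, 1, "cells/mm2"),
    rec("epithelial_t_per100_luminal", counts$epithelialT,
        counts$luminalNuclei, 100, "cells/100 luminal nuclei"),
    rec("stromal_t_density", counts$stromalT, totalStromaMm2, 1,
        "cells/mm2"))
}

#' Measure one count box against ground-truth cell records
#'
#' Applies the counting rule, the macrophage size filter and the
#' density normalisations to the planted cell table of a synthetic
#' field. Epithelial T cells are those with over half their perimeter
#' on the basement membrane (`basementContactFraction > 0.5`).
#'
#' @param box single-row box data.frame.
#' @param gt a [GroundTruth-class].
#' @return one-row data.frame of counts, areas and densities.
#' @export
measureCountBox <- function(box, gt) {
  cl <- gt@cells
  px <- gt@config@pixelSizeUm
  inBox <- countCellsInBox(box, cl)
  lum <- inBox & cl$class == "luminal"
  meanLumArea <- mean(cl$area_px[lum])
  macs <- which(inBox & cl$class == "macrophage_stromal")
  macKeep <- if (length(macs))
    sum(filterMacrophageObjects(cl$area_px[macs], meanLumArea)) else 0L
  tc <- cl$class %in% c("t_cell_epithelial", "t_cell_stromal")
  epiT <- sum(inBox & tc & cl$basementContactFraction > 0.5)
  strT <- sum(inBox & tc & cl$basementContactFraction <= 0.5)

  ri <- max(1L, floor(box$y0_px) + 1L):
    min(nrow(gt@stromaMask), ceiling(box$y0_px + box$h_px))
  ci <- max(1L, floor(box$x0_px) + 1L):
    min(ncol(gt@stromaMask), ceiling(box$x0_px + box$w_px))
  stromaMm2 <- sum(gt@stromaMask[ri, ci]) * (px / 1000)^2

  dens <- immuneDensities(
    list(stromalMac = macKeep, epithelialT = epiT, stromalT = strT,
         luminalNuclei = sum(lum)),
    intralobularStromaMm2 = stromaMm2, totalStromaMm2 = stromaMm2)
  data.frame(boxId = box$boxId,
             luminalNuclei = sum(lum), meanLuminalAreaPx = meanLumArea,
             stromalMac = macKeep, epithelialT = epiT, stromalT = strT,
             stromaMm2 = stromaMm2,
             stromalMacDensity = dens$value[1L],
             epithelialTPer100 = dens$value[2L],
             stromalTDensity = dens$value[3L])
}

## ---- tertiary lymphoid structures -----------------------------------

pointInPolygon <- function(x, y, polyX, polyY) {
  n <- length(polyX)
  inside <- rep(FALSE, length(x))
  j <- n
  for (k in seq_len(n)) {
    cross <- (polyY[k] > y) != (polyY[j] > y)
    xint <- (polyX[j] - polyX[k]) * (y - polyY[k]) /
      (polyY[j] - polyY[k]) + polyX[k]
    inside <- xor(inside, cross & x < xint)
    j <- k
  }
  inside
}

distToPolygon <- function(x, y, polyX, polyY) {
  n <- length(polyX)
  best <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    vx <- polyX[k2] - polyX[k]; vy <- polyY[k2] - polyY[k]
    L2 <- vx^2 + vy^2
    tt <- if (L2 > 0)
      pmin(1, pmax(0, ((x - polyX[k]) * vx + (y - polyY[k]) * vy) / L2))
    else 0
    ex <- polyX[k] + tt * vx - x; ey <- polyY[k] + tt * vy - y
    best <- pmin(best, sqrt(ex^2 + ey^2))
  }
  best
}

#' Detect tertiary lymphoid structures
#'
#' A TLS is a discrete B lymphocyte aggregate with a distinct adjacent
#' T lymphocyte area: B cells are clustered by single linkage at
#' `radiusUm`; a cluster of at least `minB` cells qualifies iff at
#' least `minT` T cells lie within an annulus of `tAnnulusUm` around
#' its convex hull while the hull interior remains B dominated
#' (interior T fraction below `maxInteriorTFrac`). Density is the
#' number of qualifying structures per mm^2 of analysed tissue.
#'
#' @param bCells,tCells data.frames with `x_px`, `y_px`.
#' @param tissueAreaMm2 analysed tissue area (mm^2), > 0.
#' @param pixelSizeUm micrometres per pixel.
#' @param radiusUm clustering radius (default 30 um).
#' @param minB minimum B cells per aggregate (default 20).
#' @param tAnnulusUm adjacent T-zone annulus width (default 50 um).
#' @param minT minimum T cells in the annulus (default 20).
#' @param maxInteriorTFrac maximum interior T fraction (default 0.3).
#' @return list with `tls` (data.frame: one row per B aggregate,
#'   qualifying or not) and `densityMm2`.
#' @export
detectTLS <- function(bCells, tCells, tissueAreaMm2, pixelSizeUm,
                      radiusUm = 30, minB = 20L, tAnnulusUm = 50,
                      minT = 20L, maxInteriorTFrac = 0.3) {
  if (!is.finite(tissueAreaMm2) || tissueAreaMm2 <= 0)
    stop("tissue area must be > 0")
  empty <- data.frame(clusterId = integer(), nB = integer(),
                      nTAdjacent = integer(), interiorTFrac = numeric(),
                      qualifies = logical())
  if (!nrow(bCells))
    return(list(tls = empty, densityMm2 = 0))
  rad <- radiusUm / pixelSizeUm
  cl <- if (nrow(bCells) == 1L) 1L else {
    hc <- stats::hclust(stats::dist(bCells[, c("x_px", "y_px")]),
                        method = "single")
    stats::cutree(hc, h = rad)
  }
  rows <- list()
  for (g in unique(cl)) {
    sel <- which(cl == g)
    if (length(sel) < minB) next
    bx <- bCells$x_px[sel]; by <- bCells$y_px[sel]
    hullIdx <- grDevices::chull(bx, by)
    hx <- bx[hullIdx]; hy <- by[hullIdx]
    nT <- 0L; interiorT <- 0L
    if (nrow(tCells)) {
      insideT <- pointInPolygon(tCells$x_px, tCells$y_px, hx, hy)
      dT <- distToPolygon(tCells$x_px, tCells$y_px, hx, hy)
      nT <- sum(!insideT & dT <= tAnnulusUm / pixelSizeUm)
      interiorT <- sum(insideT)
    }
    interiorFrac <- interiorT / (interiorT + length(sel))
    rows[[length(rows) + 1L]] <- data.frame(
      clusterId = g, nB = length(sel), nTAdjacent = nT,
      interiorTFrac = interiorFrac,
      qualifies = nT >= minT && interiorFrac < maxInteriorTFrac)
  }
  tls <- if (length(rows)) do.call(rbind, rows) else empty
  list(tls = tls, densityMm2 = sum(tls$qualifies) / tissueAreaMm2)
}
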