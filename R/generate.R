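## Geometry helpers. Pixel [i, j] (1-based R indices) carries the
## 0-based coordinate (x, y) = (j - 1, i - 1); a continuous coordinate
## is attributed to the pixel whose index is its rounded value.

## Add a radially tapered disc (value * (1 - (rho/r)^2)+) into `mat`.
stampSoftDisc <- function(mat, cx, cy, r, value) {
  h <- nrow(mat); w <- ncol(mat)
  j0 <- max(1L, floor(cx - r) + 1L); j1 <- min(w, ceiling(cx + r) + 1L)
  i0 <- max(1L, floor(cy - r) + 1L); i1 <- min(h, ceiling(cy + r) + 1L)
  if (j0 > j1 || i0 > i1) return(mat)
  dx <- (j0:j1) - 1 - cx
  dy <- (i0:i1) - 1 - cy
  rho2 <- outer(dy^2, dx^2, "+")
  patch <- value * pmax(0, 1 - rho2 / r^2)
  mat[i0:i1, j0:j1] <- mat[i0:i1, j0:j1] + patch
  mat
}

## Write integer `id` into label map pixels within r of (cx, cy),
## without overwriting existing labels (first wins).
stampLabelDisc <- function(mat, cx, cy, r, id) {
  h <- nrow(mat); w <- ncol(mat)
  j0 <- max(1L, floor(cx - r) + 1L); j1 <- min(w, ceiling(cx + r) + 1L)
  i0 <- max(1L, floor(cy - r) + 1L); i1 <- min(h, ceiling(cy + r) + 1L)
  if (j0 > j1 || i0 > i1) return(mat)
  dx <- (j0:j1) - 1 - cx
  dy <- (i0:i1) - 1 - cy
  rho2 <- outer(dy^2, dx^2, "+")
  sub <- mat[i0:i1, j0:j1]
  put <- rho2 <= r^2 & sub == 0L
  sub[put] <- id
  mat[i0:i1, j0:j1] <- sub
  ## guarantee at least the centre pixel
  ic <- round(cy) + 1L; jc <- round(cx) + 1L
  if (ic >= 1L && ic <= h && jc >= 1L && jc <= w && mat[ic, jc] == 0L)
    mat[ic, jc] <- id
  mat
}

## Logical mask of pixels inside an ellipse (centre c, semi-axes a >= b,
## major axis along unit vector v), restricted to a bounding box.
ellipseMask <- function(h, w, cx, cy, a, b, v) {
  r <- max(a, b)
  j0 <- max(1L, floor(cx - r) + 1L); j1 <- min(w, ceiling(cx + r) + 1L)
  i0 <- max(1L, floor(cy - r) + 1L); i1 <- min(h, ceiling(cy + r) + 1L)
  m <- matrix(FALSE, h, w)
  if (j0 > j1 || i0 > i1) return(m)
  dx <- (j0:j1) - 1 - cx
  dy <- (i0:i1) - 1 - cy
  ## rotate into the ellipse frame
  px <- outer(dy * v[2L], dx * v[1L], "+")      # along-axis component
  py <- outer(dy * v[1L], -dx * v[2L], "+")     # perpendicular
  m[i0:i1, j0:j1] <- (px / a)^2 + (py / b)^2 <= 1
  m
}

## Distance (px) from each pixel of a bounding box around `poly` to the
## open polyline; returns list(i0, j0, d) with d a matrix over the box.
polylineDistance <- function(h, w, poly, margin) {
  j0 <- max(1L, floor(min(poly$x) - margin) + 1L)
  j1 <- min(w, ceiling(max(poly$x) + margin) + 1L)
  i0 <- max(1L, floor(min(poly$y) - margin) + 1L)
  i1 <- min(h, ceiling(max(poly$y) + margin) + 1L)
  xs <- (j0:j1) - 1; ys <- (i0:i1) - 1
  d2 <- matrix(Inf, length(ys), length(xs))
  for (k in seq_len(nrow(poly) - 1L)) {
    x1 <- poly$x[k]; y1 <- poly$y[k]
    x2 <- poly$x[k + 1L]; y2 <- poly$y[k + 1L]
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx^2 + vy^2
    if (L2 == 0) next
    ## projection parameter t for every pixel, clamped to the segment
    tx <- outer(rep(1, length(ys)), (xs - x1) * vx)
    ty <- outer((ys - y1) * vy, rep(1, length(xs)))
    tt <- pmin(1, pmax(0, (tx + ty) / L2))
    ex <- outer(rep(1, length(ys)), xs) - (x1 + tt * vx)
    ey <- outer(ys, rep(1, length(xs))) - (y1 + tt * vy)
    d2 <- pmin(d2, ex^2 + ey^2)
  }
  list(i0 = i0, j0 = j0, d = sqrt(d2))
}

## Point at arc length s along an open polyline with cumulative arc
## column s_px; also returns the unit normal there.
polylinePointAt <- function(poly, s) {
  sp <- poly$s_px
  k <- findInterval(s, sp, all.inside = TRUE)
  f <- (s - sp[k]) / (sp[k + 1L] - sp[k])
  x <- poly$x[k] + f * (poly$x[k + 1L] - poly$x[k])
  y <- poly$y[k] + f * (poly$y[k + 1L] - poly$y[k])
  vx <- poly$x[k + 1L] - poly$x[k]; vy <- poly$y[k + 1L] - poly$y[k]
  L <- sqrt(vx^2 + vy^2)
  list(x = x, y = y, nx = -vy / L, ny = vx / L)
}

## Jittered arc positions with mean gap `gap` and cv `cv` over [0, len].
periodicArcPositions <- function(len, gap, cv, phase = NULL) {
  if (len <= gap) return(numeric())
  if (is.null(phase)) phase <- runif(1, 0, gap)
  n <- ceiling(len / gap) + 5L
  gaps <- pmax(0.3 * gap, rnorm(n, gap, cv * gap))
  pos <- phase + cumsum(c(0, gaps))
  pos[pos < len]
}

## Nuclei exclude each other: for any pair closer than
## 0.85 * (r1 + r2), an immune cell displaces an epithelial nucleus
## (intercalated cells push their neighbours aside); otherwise the
## later-placed cell of the pair is thinned out.
resolveNucleusCollisions <- function(cl, factor = 0.85) {
  n <- nrow(cl)
  if (n < 2L) return(cl)
  r <- sqrt(cl$area_px / pi)
  epiClass <- cl$class %in% c("luminal", "basal")
  keep <- rep(TRUE, n)
  ## spatial binning keeps the pair scan near-linear
  binSize <- max(4 * max(r), 1)
  bx <- floor(cl$x_px / binSize); by <- floor(cl$y_px / binSize)
  key <- paste(bx, by)
  bins <- split(seq_len(n), key)
  lookup <- new.env(parent = emptyenv())
  for (nm in names(bins)) assign(nm, bins[[nm]], envir = lookup)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (dx in -1:1) for (dy in -1:1) {
      nm <- paste(bx[i] + dx, by[i] + dy)
      js <- if (exists(nm, envir = lookup)) get(nm, envir = lookup) else NULL
      for (j in js) {
        if (j <= i || !keep[j] || !keep[i]) next
        lim <- factor * (r[i] + r[j])
        if ((cl$x_px[i] - cl$x_px[j])^2 + (cl$y_px[i] - cl$y_px[j])^2 <
            lim^2) {
          if (epiClass[i] && !epiClass[j]) keep[i] <- FALSE
          else if (!epiClass[i] && epiClass[j]) keep[j] <- FALSE
          else keep[j] <- FALSE
        }
      }
    }
  }
  cl[keep, , drop = FALSE]
}

emptyCellTable <- function() {
  data.frame(cellId = integer(), class = character(),
             x_px = numeric(), y_px = numeric(), area_px = numeric(),
             ki67 = logical(), basementContactFraction = numeric(),
             lobuleId = integer(), ductId = integer(), axisU = numeric(),
             stringsAsFactors = FALSE)
}

cellRow <- function(class, x, y, areaPx, bcf = 0, lobule = NA_integer_,
                    duct = NA_integer_, u = NA_real_) {
  data.frame(cellId = NA_integer_, class = class, x_px = x, y_px = y,
             area_px = areaPx, ki67 = FALSE,
             basementContactFraction = bcf, lobuleId = lobule,
             ductId = duct, axisU = u, stringsAsFactors = FALSE)
}

#' Generate a synthetic developing-TDLU field with planted ground truth
#'
#' Builds the geometry the downstream stages quantify: lobules modelled
#' as ellipses along a growth axis, each holding a central duct and a
#' set of ductule rings with a two-layer (luminal/basal) epithelium;
#' intraepithelial macrophages at jittered periodic arc spacing along
#' ducts and ductules; stromal macrophages denser centrally than
#' peripherally; intraepithelial and stromal T lymphocytes; and B/T
#' aggregates organised as tertiary lymphoid structures. Ki67 status is
#' then assigned by [assignKi67()] with the configured baseline and
#' axis gradient.
#'
#' The output is deterministic given `(seed, config, ageGroup)`; every
#' stage consumes an independent child stream of the root seed.
#'
#' @param config a [SimConfig-class]; `NA` group-dependent slots are
#'   filled from [agePreset()].
#' @param ageGroup `"young"` or `"old"`.
#' @return a [GroundTruth-class].
#' @examples
#' gt <- generateField(simConfig(seed = 1, nLobules = 1,
#'                               fieldWidthPx = 500, fieldHeightPx = 400),
#'                     "young")
#' table(cells(gt)$class)
#' @export
generateField <- function(config, ageGroup = c("young", "old")) {
  ageGroup <- match.arg(ageGroup)
  validObject(config)
  config <- applyAgePreset(config, ageGroup)
  w <- config@fieldWidthPx; h <- config@fieldHeightPx
  px <- config@pixelSizeUm
  v <- config@lobuleAxis

  ## physical building blocks (um)
  rNucL <- 3.0        # luminal nucleus radius
  rNucB <- 2.2        # basal nucleus radius
  lumenR <- 18        # ductule lumen radius
  spacingL <- 7.5     # luminal nucleus spacing along the layer
  spacingB <- 8.5
  sepLB <- 3.2        # cytoplasmic clearance between the two layers
  rMacE <- 2.0        # intercalated macrophage nucleus radius
  rTepi <- 1.8        # intraepithelial T cell radius
  lumOff <- rNucL                       # luminal ring offset from lumen
  basOff <- 2 * rNucL + sepLB + rNucB   # basal ring offset
  epiIn <- lumenR                       # inner epithelium radius
  epiOut <- lumenR + basOff + rNucB + 0.5
  midLayer <- lumenR + lumOff + (basOff - lumOff) / 2  # macrophage/T niche
  ductHalf <- 8                         # duct lumen half-width

  toPx <- function(um) um / px

  epi <- matrix(FALSE, h, w)
  lumen <- matrix(FALSE, h, w)
  paren <- matrix(FALSE, h, w)
  cellList <- list(emptyCellTable())
  ducts <- list()
  ductId <- 0L

  lobules <- data.frame(lobuleId = integer(), cx = numeric(),
                        cy = numeric(), a = numeric(), b = numeric(),
                        axisX = numeric(), axisY = numeric())

  withSeed(childSeed(config@seed, "geometry"), {
    if (config@nLobules > 0L) {
      ## chord of the field rectangle through its centre along v
      cx0 <- (w - 1) / 2; cy0 <- (h - 1) / 2
      tEdge <- function(dir) {
        tt <- c(if (dir[1L] != 0) c((0 - cx0) / dir[1L], (w - 1 - cx0) / dir[1L]),
                if (dir[2L] != 0) c((0 - cy0) / dir[2L], (h - 1 - cy0) / dir[2L]))
        min(tt[tt > 0])
      }
      L <- tEdge(v) + tEdge(-v)
      perp <- c(-v[2L], v[1L])
      Lp <- tEdge(perp) + tEdge(perp * -1)
      slot <- L / config@nLobules
      a <- 0.46 * slot
      b <- min(0.90 * a, 0.42 * Lp)
      for (li in seq_len(config@nLobules)) {
        tc <- -L / 2 + (li - 0.5) * slot
        off <- runif(1, -0.05, 0.05) * Lp
        cx <- cx0 + tc * v[1L] + off * perp[1L]
        cy <- cy0 + tc * v[2L] + off * perp[2L]
        lobules <- rbind(lobules, data.frame(
          lobuleId = li, cx = cx, cy = cy, a = a, b = b,
          axisX = v[1L], axisY = v[2L]))
        paren <- paren | ellipseMask(h, w, cx, cy, a, b, v)

        ## axis-u of a point: projection onto v across the ellipse extent
        uOf <- function(x, y)
          pmin(1, pmax(0, (((x - cx) * v[1L] + (y - cy) * v[2L]) + a) / (2 * a)))

        ## ---- central duct: gently wavy open polyline along the axis
        ductId <- ductId + 1L
        tt <- seq(-0.8 * a, 0.8 * a, by = toPx(10))
        wob <- 0.08 * b * sin(tt / a * pi * runif(1, 1.5, 2.5) +
                              runif(1, 0, 2 * pi))
        poly <- data.frame(x = cx + tt * v[1L] + wob * perp[1L],
                           y = cy + tt * v[2L] + wob * perp[2L])
        seglen <- sqrt(diff(poly$x)^2 + diff(poly$y)^2)
        poly$s_px <- c(0, cumsum(seglen))
        lenUm <- max(poly$s_px) * px

        pd <- polylineDistance(h, w, poly, toPx(epiOut - lumenR + ductHalf) + 2)
        ii <- pd$i0:(pd$i0 + nrow(pd$d) - 1L)
        jj <- pd$j0:(pd$j0 + ncol(pd$d) - 1L)
        dUm <- pd$d * px
        lumen[ii, jj] <- lumen[ii, jj] | (dUm < ductHalf)
        epi[ii, jj] <- epi[ii, jj] |
          (dUm >= ductHalf & dUm < ductHalf + (epiOut - epiIn))

        ## duct nuclei: two layers on both sides
        for (side in c(-1, 1)) {
          for (layer in c("luminal", "basal")) {
            off <- if (layer == "luminal") ductHalf + lumOff else
              ductHalf + basOff
            rr <- if (layer == "luminal") rNucL else rNucB
            sp <- if (layer == "luminal") spacingL else spacingB
            ss <- periodicArcPositions(max(poly$s_px), toPx(sp), 0.10)
            for (s in ss) {
              p <- polylinePointAt(poly, s)
              x <- p$x + side * toPx(off) * p$nx
              y <- p$y + side * toPx(off) * p$ny
              if (x < 0 || x > w - 1 || y < 0 || y > h - 1) next
              cellList[[length(cellList) + 1L]] <- cellRow(
                layer, x, y, pi * toPx(rr)^2,
                bcf = if (layer == "basal") 1 else 0,
                lobule = li, duct = ductId, u = uOf(x, y))
            }
          }
        }

        ## duct intraepithelial macrophages, alternating sides
        macS <- periodicArcPositions(lenUm, config@macrophageSpacingUm,
                                     config@macrophageSpacingCv)
        side <- 1
        for (s in macS) {
          p <- polylinePointAt(poly, toPx(s))
          x <- p$x + side * toPx(ductHalf + lumOff + (basOff - lumOff) / 2) * p$nx
          y <- p$y + side * toPx(ductHalf + lumOff + (basOff - lumOff) / 2) * p$ny
          side <- -side
          if (x < 0 || x > w - 1 || y < 0 || y > h - 1) next
          cellList[[length(cellList) + 1L]] <- cellRow(
            "macrophage_intraepithelial", x, y, pi * toPx(rMacE)^2,
            bcf = 0.5, lobule = li, duct = ductId, u = uOf(x, y))
        }
        polyOut <- poly; names(polyOut) <- c("x_px", "y_px", "s_px")
        polyOut$s_um <- polyOut$s_px * px
        ducts[[length(ducts) + 1L]] <- list(
          ductId = ductId, lobuleId = li, type = "duct", closed = FALSE,
          polyline = polyOut, lengthUm = lenUm, macArcUm = sort(macS))

        ## ---- ductule rings on a jittered hex grid inside the ellipse
        ## ductules cluster in an inner core, leaving a band of loose
        ## intralobular stroma inside the lobule boundary
        hexStep <- toPx(4.5 * lumenR)
        aIn <- 0.80 * a; bIn <- 0.80 * b
        gx <- seq(-aIn + toPx(epiOut) + 2, aIn - toPx(epiOut) - 2,
                  by = hexStep)
        gy <- seq(-bIn + toPx(epiOut) + 2, bIn - toPx(epiOut) - 2,
                  by = hexStep * 0.866)
        ## centre the lattice so the seq() remainder does not thin the
        ## leading edge
        if (length(gx)) gx <- gx + (aIn - toPx(epiOut) - 2 - max(gx)) / 2
        if (length(gy)) gy <- gy + (bIn - toPx(epiOut) - 2 - max(gy)) / 2
        if (length(gx) && length(gy)) for (yi in seq_along(gy)) {
          for (xi in seq_along(gx)) {
            ox <- gx[xi] + (yi %% 2) * hexStep / 2 + runif(1, -2, 2)
            oy <- gy[yi] + runif(1, -2, 2)
            mrg <- toPx(epiOut) + 2
            if ((ox / (aIn - mrg))^2 + (oy / (bIn - mrg))^2 > 1) next
            dcx <- cx + ox * v[1L] - oy * v[2L]
            dcy <- cy + ox * v[2L] + oy * v[1L]
            ## keep clear of the central duct
            dmin <- min(sqrt((poly$x - dcx)^2 + (poly$y - dcy)^2))
            if (dmin * px < epiOut + ductHalf + epiOut - epiIn + 4) next
            ductId <- ductId + 1L
            uD <- uOf(dcx, dcy)

            ## annulus masks
            rr <- toPx(epiOut)
            j0 <- max(1L, floor(dcx - rr) + 1L)
            j1 <- min(w, ceiling(dcx + rr) + 1L)
            i0 <- max(1L, floor(dcy - rr) + 1L)
            i1 <- min(h, ceiling(dcy + rr) + 1L)
            dxs <- (j0:j1) - 1 - dcx; dys <- (i0:i1) - 1 - dcy
            rho <- sqrt(outer(dys^2, dxs^2, "+")) * px
            lumen[i0:i1, j0:j1] <- lumen[i0:i1, j0:j1] | (rho < epiIn)
            epi[i0:i1, j0:j1] <- epi[i0:i1, j0:j1] |
              (rho >= epiIn & rho < epiOut)

            circ <- function(rUm) 2 * pi * rUm
            for (layer in c("luminal", "basal")) {
              rad <- if (layer == "luminal") epiIn + lumOff else
                epiIn + basOff
              rr2 <- if (layer == "luminal") rNucL else rNucB
              sp <- if (layer == "luminal") spacingL else spacingB
              ss <- periodicArcPositions(circ(rad), sp, 0.10)
              for (s in ss) {
                th <- s / rad
                x <- dcx + toPx(rad) * cos(th)
                y <- dcy + toPx(rad) * sin(th)
                if (x < 0 || x > w - 1 || y < 0 || y > h - 1) next
                cellList[[length(cellList) + 1L]] <- cellRow(
                  layer, x, y, pi * toPx(rr2)^2,
                  bcf = if (layer == "basal") 1 else 0,
                  lobule = li, duct = ductId, u = uD)
              }
            }

            ## ductule macrophages + epithelial T cells at mid-layer
            circM <- circ(midLayer)
            macS <- periodicArcPositions(circM, config@macrophageSpacingUm,
                                         config@macrophageSpacingCv)
            for (s in macS) {
              th <- s / midLayer
              x <- dcx + toPx(midLayer) * cos(th)
              y <- dcy + toPx(midLayer) * sin(th)
              if (x < 0 || x > w - 1 || y < 0 || y > h - 1) next
              cellList[[length(cellList) + 1L]] <- cellRow(
                "macrophage_intraepithelial", x, y, pi * toPx(rMacE)^2,
                bcf = 0.5, lobule = li, duct = ductId, u = uD)
            }
            nLum <- floor(circ(epiIn + lumOff) / spacingL)
            nT <- rpois(1L, config@tEpiPer100 / 100 * nLum)
            if (nT > 0) for (s in runif(nT, 0, circM)) {
              th <- s / midLayer
              x <- dcx + toPx(midLayer) * cos(th)
              y <- dcy + toPx(midLayer) * sin(th)
              if (x < 0 || x > w - 1 || y < 0 || y > h - 1) next
              cellList[[length(cellList) + 1L]] <- cellRow(
                "t_cell_epithelial", x, y, pi * toPx(rTepi)^2,
                bcf = runif(1, 0.55, 0.95), lobule = li, duct = ductId,
                u = uD)
            }

            ## closed trace: circle polyline at the macrophage niche
            th <- seq(0, 2 * pi, length.out = 73L)
            polyC <- data.frame(
              x_px = dcx + toPx(midLayer) * cos(th),
              y_px = dcy + toPx(midLayer) * sin(th),
              s_px = toPx(midLayer) * th)
            polyC$s_um <- polyC$s_px * px
            ducts[[length(ducts) + 1L]] <- list(
              ductId = ductId, lobuleId = li, type = "ductule",
              closed = TRUE, polyline = polyC, lengthUm = circM,
              macArcUm = sort(macS))
          }
        }
      }
    }
  })

  epi <- epi & !lumen
  stroma <- paren & !epi & !lumen

  ## ---- stromal populations -------------------------------------------
  withSeed(childSeed(config@seed, "stroma"), {
    areaPxMm2 <- (px / 1000)^2          # mm^2 per pixel
    if (any(stroma)) {
      distFat <- EBImage::distmap(paren * 1L) * px   # um to the fat pad
      ## basement-membrane clearance: stromal nuclei keep off the
      ## epithelial outer surface
      distEpi <- EBImage::distmap((!epi) * 1L) * px  # um to epithelium
      open <- stroma & distEpi > 3
      central <- stroma & distFat > 200
      periph <- stroma & !central
      ## counts are planted per unit of full stromal area; positions
      ## are drawn in open stroma (off the basement membrane)
      sampleIn <- function(mask, density, class, areaUm2, bcfMax = 0.2) {
        idx <- which(mask & open)
        if (!length(idx) || density <= 0) return(NULL)
        nn <- rpois(1L, density * sum(mask) * areaPxMm2)
        if (nn == 0L) return(NULL)
        pick <- sample(idx, nn, replace = TRUE)
        rc <- arrayInd(pick, dim(mask))
        do.call(rbind, lapply(seq_len(nn), function(k)
          cellRow(class,
                  pmin(ncol(mask) - 1, pmax(0, rc[k, 2L] - 1 + runif(1, -0.5, 0.5))),
                  pmin(nrow(mask) - 1, pmax(0, rc[k, 1L] - 1 + runif(1, -0.5, 0.5))),
                  areaUm2 / px^2, bcf = runif(1, 0, bcfMax))))
      }
      cellList[[length(cellList) + 1L]] <-
        sampleIn(central, config@stromalMacDensityCentral,
                 "macrophage_stromal", pi * 2.6^2)
      cellList[[length(cellList) + 1L]] <-
        sampleIn(periph, config@stromalMacDensityPeripheral,
                 "macrophage_stromal", pi * 2.6^2)
      cellList[[length(cellList) + 1L]] <-
        sampleIn(stroma, config@stromalTDensity, "t_cell_stromal",
                 pi * 2^2)

      ## tertiary lymphoid structures: B core + adjacent T ring
      if (config@nTls > 0L) {
        deep <- which(open & distFat > 35 & distEpi > 25)
        if (length(deep)) {
          picks <- sample(deep, min(config@nTls, length(deep)))
          for (pk in picks) {
            rc <- arrayInd(pk, dim(stroma))
            ccx <- rc[2L] - 1; ccy <- rc[1L] - 1
            nB <- 60L; nT <- 80L
            thB <- runif(nB, 0, 2 * pi); rB <- toPx(30) * sqrt(runif(nB))
            thT <- runif(nT, 0, 2 * pi)
            rT <- toPx(sqrt(runif(nT, 30^2, 60^2)))
            bx <- pmin(w - 1, pmax(0, ccx + rB * cos(thB)))
            by <- pmin(h - 1, pmax(0, ccy + rB * sin(thB)))
            tx <- pmin(w - 1, pmax(0, ccx + rT * cos(thT)))
            ty <- pmin(h - 1, pmax(0, ccy + rT * sin(thT)))
            keepB <- open[cbind(round(by) + 1L, round(bx) + 1L)]
            keepT <- open[cbind(round(ty) + 1L, round(tx) + 1L)]
            cellList[[length(cellList) + 1L]] <- do.call(rbind, c(
              lapply(which(keepB), function(k)
                cellRow("b_cell", bx[k], by[k], pi * toPx(2)^2)),
              lapply(which(keepT), function(k)
                cellRow("t_cell_stromal", tx[k], ty[k], pi * toPx(2)^2))))
          }
        }
      }
    }
  })

  cellsDf <- do.call(rbind, cellList)
  cellsDf <- resolveNucleusCollisions(cellsDf)
  if (nrow(cellsDf)) cellsDf$cellId <- seq_len(nrow(cellsDf))
  rownames(cellsDf) <- NULL

  gt <- new("GroundTruth", cells = cellsDf, epitheliumMask = epi,
            stromaMask = stroma, lobules = lobules, ductTraces = ducts,
            config = config, ageGroup = ageGroup)
  assignKi67(gt, config@ki67P0, config@ki67Slope)
}

#' Assign Ki67 positivity along the lobule growth axis
#'
#' Each epithelial nucleus (luminal or basal) becomes Ki67 positive
#' with probability `logistic(logit(p0) + slope * (u - 0.5))` where `u`
#' is its normalised axis coordinate (1 = leading edge). Non-epithelial
#' cells are untouched. With `slope = 0` positivity is uniform at `p0`;
#' positive slopes polarise proliferation towards the advancing tip.
#'
#' @param gt a [GroundTruth-class] whose epithelial cells carry `axisU`.
#' @param p0 baseline positivity probability, in (0, 1).
#' @param slope logistic slope per normalised axis unit.
#' @param seed optional; defaults to a child stream of the config seed.
#' @return the modified [GroundTruth-class].
#' @export
assignKi67 <- function(gt, p0, slope, seed = NULL) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly inside (0, 1)")
  if (is.null(seed)) seed <- childSeed(gt@config@seed, "ki67")
  cl <- gt@cells
  isEpi <- cl$class %in% c("luminal", "basal")
  if (any(isEpi)) {
    u <- cl$axisU[isEpi]
    if (anyNA(u)) stop("epithelial cells must carry an axis coordinate")
    p <- plogis(qlogis(p0) + slope * (u - 0.5))
    withSeed(seed, {
      cl$ki67[isEpi] <- runif(sum(isEpi)) < p
    })
  }
  gt@cells <- cl
  gt
}
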