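## Otsu threshold of a value vector (wraps EBImage::otsu on a 1-row
## image after scaling to [0, 1]).
otsuOf <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1L])
  sc <- (values - rng[1L]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(sc, nrow = 1L)),
                      range = c(0, 1), levels = levels)
  rng[1L] + th * diff(rng)
}

#' Default segmentation parameters
#'
#' Physical defaults converted to pixels through the field's pixel
#' size, so the same settings work at full or reduced scan scale:
#' nucleus area gates 4.1-104 um^2 (80-2000 px^2 at a 0.2276 um/px
#' scan), smoothing sigma 1 px at full scale, epithelium density
#' bandwidth 5.7 um (25 px), closing radius 3.4 um (15 px).
#'
#' @param pixelSizeUm micrometres per pixel of the image.
#' @return named list of parameters in pixel units.
#' @export
segmentationParams <- function(pixelSizeUm) {
  fullPx <- 0.2276
  list(
    sigmaPx = max(0.8, 1 * fullPx / pixelSizeUm),
    beta = 0.15,
    concFloor = 0.15,
    dabFloor = 0.30,
    dabObjectFrac = 0.5,
    peakFrac = 0.45,
    minAreaPx = 80 * (fullPx / pixelSizeUm)^2,
    maxAreaPx = 2000 * (fullPx / pixelSizeUm)^2,
    watershedTol = 0.3,
    closingUm = 5.0,
    expandUm = 1.0,
    holeAreaUm2 = 250,
    minRegionUm2 = 500
  )
}

#' Segment Ki67+/Ki67- nuclei from a normalised H-DAB field
#'
#' Deterministic classical pipeline producing the three-class nuclei
#' mask contract (Ki67+ nuclei / Ki67- nuclei / background-other):
#' colour deconvolution to haematoxylin and DAB concentration maps,
#' Gaussian smoothing, per-channel Otsu thresholds restricted to
#' tissue pixels with an absolute concentration floor, distance
#' transform watershed to split touching nuclei, an area gate, and
#' object-level phenotype assignment where DAB wins overlap (a Ki67+
#' nucleus is counterstained too).
#'
#' @param image normalised [ImageField-class] or RGB array.
#' @param stain a [StainModel-class] used for deconvolution.
#' @param params list from [segmentationParams()]; defaults are
#'   derived from the image pixel size.
#' @param pixelSizeUm required when `image` is a bare array.
#' @param fieldId identifier stored in the output.
#' @return a [MaskSet-class] with the nuclei label maps filled and an
#'   all-FALSE epithelium mask (see [segmentEpithelium()]).
#' @export
segmentNuclei <- function(image, stain, params = NULL,
                          pixelSizeUm = NULL, fieldId = "field") {
  if (is(image, "ImageField")) {
    if (is.null(pixelSizeUm)) pixelSizeUm <- image@pixelSizeUm
    if (fieldId == "field") fieldId <- image@fieldId
    rgb <- image@rgb
  } else rgb <- image
  if (is.null(pixelSizeUm))
    stop("pixelSizeUm is required for a bare array input")
  if (length(rgb) == 0 || all(is.na(rgb))) stop("empty image")
  if (is.null(params)) params <- segmentationParams(pixelSizeUm)

  od <- rgbToOD(rgb, stain@backgroundIntensity)
  conc <- fitConcentrations(od, stain)
  hMap <- EBImage::gblur(conc[, , 1L], sigma = params$sigmaPx)
  dMap <- EBImage::gblur(conc[, , 2L], sigma = params$sigmaPx)
  odNorm <- sqrt(od[, , 1L]^2 + od[, , 2L]^2 + od[, , 3L]^2)
  tissue <- odNorm > params$beta

  h <- nrow(hMap); w <- ncol(hMap)
  empty <- function() new("MaskSet", epithelium = matrix(FALSE, h, w),
                          ki67Pos = matrix(0L, h, w),
                          ki67Neg = matrix(0L, h, w),
                          fieldId = fieldId, pixelSizeUm = pixelSizeUm)
  if (!any(tissue)) return(empty())

  ## two-pass thresholding: an Otsu/floored first cut, then both
  ## channels re-thresholded at the same fraction of their estimated
  ## modal blob amplitude, so Ki67+ and Ki67- nucleus pixel areas are
  ## measured on the same footing (the pixel-area ratio is otherwise
  ## biased by unequal chromogen intensities)
  ampOf <- function(map, thr) {
    lb <- EBImage::bwlabel(map > thr)
    idx <- which(lb > 0L)
    if (length(idx) < 10L) return(Inf)
    stats::median(tapply(map[idx], lb[idx], max))
  }
  thH0 <- max(otsuOf(hMap[tissue]), params$concFloor)
  dVals <- dMap[tissue]
  thD0 <- if (any(dVals > params$dabFloor))
    max(otsuOf(dVals[dVals > 0.5 * params$dabFloor]), params$dabFloor)
  else Inf
  thH <- max(params$peakFrac * ampOf(hMap, thH0), params$concFloor)
  thD <- if (is.finite(thD0))
    max(params$peakFrac * ampOf(dMap, thD0), params$dabFloor) else Inf
  hMask <- hMap > thH
  dMask <- dMap > thD
  nucMask <- hMask | dMask
  if (!any(nucMask)) return(empty())

  dist <- EBImage::distmap(nucMask * 1)
  labels <- EBImage::watershed(dist, tolerance = params$watershedTol, ext = 1)
  labels <- EBImage::imageData(labels)
  storage.mode(labels) <- "integer"

  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= params$minAreaPx & areas <= params$maxAreaPx)
  if (!length(keep)) return(empty())

  ## object-level DAB fraction decides the phenotype
  idx <- which(labels > 0L)
  lab <- labels[idx]
  inKeep <- lab %in% keep
  idx <- idx[inKeep]; lab <- lab[inKeep]
  dabFrac <- rowsum(as.numeric(dMask[idx]), lab) /
    rowsum(rep(1, length(lab)), lab)
  objIds <- as.integer(rownames(dabFrac))
  isPos <- dabFrac[, 1L] >= params$dabObjectFrac

  posIds <- objIds[isPos]; negIds <- objIds[!isPos]
  newPos <- integer(max(objIds)); newNeg <- integer(max(objIds))
  newPos[posIds] <- seq_along(posIds)
  newNeg[negIds] <- length(posIds) + seq_along(negIds)

  ki67Pos <- matrix(0L, h, w); ki67Neg <- matrix(0L, h, w)
  posSel <- newPos[lab] > 0L
  ki67Pos[idx[posSel]] <- newPos[lab[posSel]]
  negSel <- newNeg[lab] > 0L
  ki67Neg[idx[negSel]] <- newNeg[lab[negSel]]

  new("MaskSet", epithelium = matrix(FALSE, h, w),
      ki67Pos = ki67Pos, ki67Neg = ki67Neg,
      fieldId = fieldId, pixelSizeUm = pixelSizeUm)
}

#' Segment the epithelium mask
#'
#' Produces the binary 'epithelium' vs 'background/other' mask from
#' nuclear coverage: the union of all detected nucleus pixels is
#' morphologically closed with a disc spanning the inter-nucleus
#' spacing (a uniform-kernel density with hard threshold), expanded by
#' a thin cytoplasm margin, small holes are filled and small
#' components removed. Lumina (large holes) stay open so the mask
#' traces the epithelial band itself, and isolated stromal nuclei are
#' dropped with the small components.
#'
#' @param masks a [MaskSet-class] from [segmentNuclei()] (its nuclei
#'   maps supply the coverage), or `NULL` to compute them.
#' @param image,stain used only when `masks` is `NULL`.
#' @param params list from [segmentationParams()].
#' @return the input [MaskSet-class] with the epithelium slot filled.
#' @export
segmentEpithelium <- function(masks = NULL, image = NULL, stain = NULL,
                              params = NULL) {
  if (is.null(masks)) {
    if (is.null(image) || is.null(stain))
      stop("either masks or (image, stain) must be given")
    masks <- segmentNuclei(image, stain, params)
  }
  pixelSizeUm <- masks@pixelSizeUm
  if (is.null(params)) params <- segmentationParams(pixelSizeUm)
  nuc <- (masks@ki67Pos > 0L) | (masks@ki67Neg > 0L)
  h <- nrow(nuc); w <- ncol(nuc)
  if (!any(nuc)) {
    masks@epithelium <- matrix(FALSE, h, w)
    return(masks)
  }
  closePx <- max(1L, round(params$closingUm / pixelSizeUm))
  mask <- EBImage::closing(nuc, EBImage::makeBrush(2L * closePx + 1L,
                                                   shape = "disc")) > 0
  expandPx <- max(1L, round(params$expandUm / pixelSizeUm))
  mask <- EBImage::dilate(mask, EBImage::makeBrush(2L * expandPx + 1L,
                                                   shape = "disc")) > 0

  ## fill only holes smaller than holeArea (lumina stay open)
  holes <- EBImage::bwlabel(!mask)
  border <- unique(c(holes[1L, ], holes[h, ], holes[, 1L], holes[, w]))
  holeAreas <- tabulate(holes[holes > 0L])
  holeAreaPx <- params$holeAreaUm2 / pixelSizeUm^2
  fill <- setdiff(which(holeAreas < holeAreaPx), border)
  if (length(fill)) mask[holes %in% fill] <- TRUE

  comp <- EBImage::bwlabel(mask)
  compAreas <- tabulate(comp[comp > 0L])
  minRegionPx <- params$minRegionUm2 / pixelSizeUm^2
  drop <- which(compAreas < minRegionPx)
  if (length(drop)) mask[comp %in% drop] <- FALSE

  masks@epithelium <- mask
  masks
}

#' Extract nucleus centroid records from a mask set
#'
#' One record per label across both phenotype maps: unweighted pixel
#' centroid (0-based coordinates), pixel area, phenotype, an
#' epithelial flag (centroid pixel inside the epithelium mask) and a
#' boundary flag for objects touching the field edge.
#'
#' @param masks a [MaskSet-class].
#' @return data.frame sorted by `nucleusId` with columns `nucleusId`,
#'   `x_px`, `y_px`, `area_px`, `phenotype`, `epithelial`, `boundary`.
#' @export
extractCentroids <- function(masks) {
  h <- nrow(masks@ki67Pos); w <- ncol(masks@ki67Pos)
  one <- function(lab, phen) {
    idx <- which(lab > 0L)
    if (!length(idx)) return(NULL)
    ids <- lab[idx]
    rc <- arrayInd(idx, dim(lab))
    n <- rowsum(rep(1, length(ids)), ids)
    sx <- rowsum(as.numeric(rc[, 2L] - 1), ids)
    sy <- rowsum(as.numeric(rc[, 1L] - 1), ids)
    onEdge <- rowsum(as.numeric(rc[, 1L] == 1L | rc[, 1L] == h |
                                  rc[, 2L] == 1L | rc[, 2L] == w), ids)
    data.frame(nucleusId = as.integer(rownames(n)),
               x_px = sx[, 1L] / n[, 1L], y_px = sy[, 1L] / n[, 1L],
               area_px = n[, 1L], phenotype = phen,
               boundary = onEdge[, 1L] > 0)
  }
  out <- rbind(one(masks@ki67Pos, "ki67_pos"),
               one(masks@ki67Neg, "ki67_neg"))
  if (is.null(out))
    return(data.frame(nucleusId = integer(), x_px = numeric(),
                      y_px = numeric(), area_px = numeric(),
                      phenotype = character(), epithelial = logical(),
                      boundary = logical()))
  ri <- pmin(h, pmax(1L, round(out$y_px) + 1L))
  ci <- pmin(w, pmax(1L, round(out$x_px) + 1L))
  out$epithelial <- masks@epithelium[cbind(ri, ci)]
  out <- out[order(out$nucleusId), c("nucleusId", "x_px", "y_px",
                                     "area_px", "phenotype",
                                     "epithelial", "boundary")]
  rownames(out) <- NULL
  out
}
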