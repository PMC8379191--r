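#' RGB image field
#'
#' An 8-bit RGB brightfield field with its physical pixel size,
#' identifier and provenance, plus (for rendered synthetic fields)
#' pixel-perfect label masks paired with the planted ground truth.
#'
#' @slot rgb numeric array `[row, col, 3]` in `[0, I0]`.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot fieldId character identifier.
#' @slot labels list of integer label matrices (`ki67Pos`, `ki67Neg`,
#'   `nuclei`) for synthetic renders; may be empty for imported images.
#' @slot provenance list (seed, marker, config echo and similar).
#' @exportClass ImageField
setClass("ImageField", representation(
  rgb = "array",
  pixelSizeUm = "numeric",
  fieldId = "character",
  labels = "list",
  provenance = "list"
))

setValidity("ImageField", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3L] != 3L)
    return("rgb must be a [row, col, 3] array")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  TRUE
})

setMethod("show", "ImageField", function(object) {
  d <- dim(object@rgb)
  cat("ImageField '", object@fieldId, "': ", d[2L], " x ", d[1L],
      " px @ ", format(object@pixelSizeUm, digits = 4), " um/px",
      if (length(object@labels)) " (with label masks)", "\n", sep = "")
})

#' @rdname mamspat-accessors
#' @export
setGeneric("rgbArray", function(object) standardGeneric("rgbArray"))
setMethod("rgbArray", "ImageField", function(object) object@rgb)

#' @rdname mamspat-accessors
#' @export
setGeneric("labelMasks", function(object) standardGeneric("labelMasks"))
setMethod("labelMasks", "ImageField", function(object) object@labels)

#' Render a ground-truth field to an H-DAB brightfield image
#'
#' Beer-Lambert rendering: per pixel, `RGB = I0 * exp(-S %*% c)` with
#' `c` the (haematoxylin, DAB) concentration pair accumulated from
#' overlapping radially tapered cell footprints, plus Gaussian noise in
#' OD space, clipped to `[0, I0]` and rounded to 8-bit levels. All
#' nuclei contribute haematoxylin; the DAB channel carries the chosen
#' marker: `"ki67"` stains Ki67+ nuclei, `"iba1"` macrophages, `"cd3"`
#' T lymphocytes (emulating marker-specific serial sections).
#'
#' Pixel-perfect label masks are emitted alongside: `ki67Pos`/`ki67Neg`
#' integer label maps over epithelial nuclei (first-wins on overlap,
#' every nucleus keeps at least its centre pixel) and a combined
#' `nuclei` map over all haematoxylin-bearing cells.
#'
#' @param gt a [GroundTruth-class].
#' @param config optional [SimConfig-class]; defaults to the config
#'   embedded in `gt`.
#' @param marker which DAB marker to render.
#' @param seed optional noise seed; defaults to a child stream.
#' @return an [ImageField-class] with label masks.
#' @export
renderField <- function(gt, config = NULL, marker = c("ki67", "iba1", "cd3"),
                        seed = NULL) {
  marker <- match.arg(marker)
  if (is.null(config)) config <- gt@config
  validObject(config)
  if (is.null(seed)) seed <- childSeed(config@seed, paste0("render-", marker))
  h <- nrow(gt@epitheliumMask); w <- ncol(gt@epitheliumMask)
  cl <- gt@cells

  haem <- matrix(0, h, w)
  dab <- matrix(0, h, w)
  labPos <- matrix(0L, h, w)
  labNeg <- matrix(0L, h, w)
  labAll <- matrix(0L, h, w)

  dabOn <- switch(marker,
    ki67 = cl$ki67 & cl$class %in% c("luminal", "basal"),
    iba1 = cl$class %in% c("macrophage_intraepithelial", "macrophage_stromal"),
    cd3 = cl$class %in% c("t_cell_epithelial", "t_cell_stromal"))

  ## stamping is inlined (rather than routed through the helper
  ## functions) so the accumulator matrices are modified in place
  patch <- function(k, r) {
    j0 <- max(1L, floor(cl$x_px[k] - r) + 1L)
    j1 <- min(w, ceiling(cl$x_px[k] + r) + 1L)
    i0 <- max(1L, floor(cl$y_px[k] - r) + 1L)
    i1 <- min(h, ceiling(cl$y_px[k] + r) + 1L)
    if (j0 > j1 || i0 > i1) return(NULL)
    dx <- (j0:j1) - 1 - cl$x_px[k]
    dy <- (i0:i1) - 1 - cl$y_px[k]
    list(i = i0:i1, j = j0:j1, rho2 = outer(dy^2, dx^2, "+"))
  }
  isEpi <- cl$class %in% c("luminal", "basal")
  if (nrow(cl)) for (k in seq_len(nrow(cl))) {
    r <- sqrt(cl$area_px[k] / pi)
    p <- patch(k, r)
    if (is.null(p)) next
    ## dense chromogen largely masks the counterstain in positive
    ## nuclei, as on real slides
    hAmp <- if (dabOn[k]) 0.05 else 1.0
    haem[p$i, p$j] <- haem[p$i, p$j] + hAmp * pmax(0, 1 - p$rho2 / r^2)
    if (dabOn[k]) {
      ## Ki67 is nuclear: the chromogen keeps the nucleus footprint;
      ## IBA1/CD3 are cytoplasmic and spill beyond it
      rd <- if (marker == "ki67") r else r * 1.6
      pd <- patch(k, rd)
      dab[pd$i, pd$j] <- dab[pd$i, pd$j] + 1.2 * pmax(0, 1 - pd$rho2 / rd^2)
    }
    hard <- p$rho2 <= r^2
    sub <- labAll[p$i, p$j]
    sub[hard & sub == 0L] <- k
    labAll[p$i, p$j] <- sub
    ## every nucleus keeps at least its centre pixel
    ic <- round(cl$y_px[k]) + 1L; jc <- round(cl$x_px[k]) + 1L
    if (ic >= 1L && ic <= h && jc >= 1L && jc <= w &&
        labAll[ic, jc] == 0L)
      labAll[ic, jc] <- k
  }
  ## phenotype maps derive from the single ownership map, so they are
  ## mutually exclusive by construction
  if (nrow(cl)) {
    isPos <- isEpi & cl$ki67
    isNeg <- isEpi & !cl$ki67
    own <- labAll > 0L
    ownId <- labAll[own]
    labPos[own] <- ifelse(isPos[ownId], ownId, 0L)
    labNeg[own] <- ifelse(isNeg[ownId], ownId, 0L)
  }

  S <- config@stainMatrix
  I0 <- config@backgroundIntensity
  rgb <- array(0, dim = c(h, w, 3L))
  withSeed(seed, {
    for (ch in 1:3) {
      od <- S[ch, 1L] * haem + S[ch, 2L] * dab
      if (config@odNoiseSd > 0)
        od <- od + matrix(rnorm(h * w, 0, config@odNoiseSd), h, w)
      rgb[, , ch] <- pmin(I0[ch], pmax(0, round(I0[ch] * exp(-od))))
    }
  })

  new("ImageField", rgb = rgb, pixelSizeUm = config@pixelSizeUm,
      fieldId = sprintf("sim-%d-%s-%s", config@seed, gt@ageGroup, marker),
      labels = list(ki67Pos = labPos, ki67Neg = labNeg, nuclei = labAll),
      provenance = list(seed = config@seed, marker = marker,
                        ageGroup = gt@ageGroup,
                        generator = "mamspat synthetic TDLU"))
}
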