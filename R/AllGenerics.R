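#' Accessors for mamspat classes
#'
#' Small accessor generics giving read access to the slots of the
#' package's S4 containers without touching `@`.
#'
#' @param object a mamspat S4 object.
#' @return the slot value; see the class documentation for types.
#' @name mamspat-accessors
NULL

#' @rdname mamspat-accessors
#' @export
setGeneric("cells", function(object) standardGeneric("cells"))

#' @rdname mamspat-accessors
#' @export
setGeneric("epitheliumMask", function(object) standardGeneric("epitheliumMask"))

#' @rdname mamspat-accessors
#' @export
setGeneric("stromaMask", function(object) standardGeneric("stromaMask"))

#' @rdname mamspat-accessors
#' @export
setGeneric("ductTraces", function(object) standardGeneric("ductTraces"))

#' @rdname mamspat-accessors
#' @export
setGeneric("parenchymaMask", function(object) standardGeneric("parenchymaMask"))

#' @rdname mamspat-accessors
#' @export
setGeneric("truthConfig", function(object) standardGeneric("truthConfig"))

#' @rdname mamspat-accessors
#' @export
setGeneric("stainMatrix", function(object) standardGeneric("stainMatrix"))

#' @rdname mamspat-accessors
#' @export
setGeneric("maxConcentrations",
           function(object) standardGeneric("maxConcentrations"))

#' @rdname mamspat-accessors
#' @export
setGeneric("backgroundIntensity",
           function(object) standardGeneric("backgroundIntensity"))

#' @rdname mamspat-accessors
#' @export
setGeneric("ki67PosLabels", function(object) standardGeneric("ki67PosLabels"))

#' @rdname mamspat-accessors
#' @export
setGeneric("ki67NegLabels", function(object) standardGeneric("ki67NegLabels"))

#' @rdname mamspat-accessors
#' @export
setGeneric("gridCounts", function(object) standardGeneric("gridCounts"))

#' @rdname mamspat-accessors
#' @export
setGeneric("zScores", function(object) standardGeneric("zScores"))

#' @rdname mamspat-accessors
#' @export
setGeneric("gridCellCentres",
           function(object) standardGeneric("gridCellCentres"))

setMethod("cells", "GroundTruth", function(object) object@cells)
setMethod("epitheliumMask", "GroundTruth", function(object) object@epitheliumMask)
setMethod("epitheliumMask", "MaskSet", function(object) object@epithelium)
setMethod("stromaMask", "GroundTruth", function(object) object@stromaMask)
setMethod("ductTraces", "GroundTruth", function(object) object@ductTraces)

## parenchyma = lobule interiors including duct/ductule lumens (the
## enclosed holes of epithelium + stroma)
setMethod("parenchymaMask", "GroundTruth", function(object) {
  m <- object@epitheliumMask | object@stromaMask
  EBImage::fillHull(m * 1L) > 0
})
setMethod("truthConfig", "GroundTruth", function(object) object@config)
setMethod("stainMatrix", "StainModel", function(object) object@stainMatrix)
setMethod("stainMatrix", "SimConfig", function(object) object@stainMatrix)
setMethod("maxConcentrations", "StainModel",
          function(object) object@maxConcentrations)
setMethod("backgroundIntensity", "StainModel",
          function(object) object@backgroundIntensity)
setMethod("backgroundIntensity", "SimConfig",
          function(object) object@backgroundIntensity)
setMethod("ki67PosLabels", "MaskSet", function(object) object@ki67Pos)
setMethod("ki67NegLabels", "MaskSet", function(object) object@ki67Neg)
setMethod("gridCounts", "GridCounts", function(object) object@counts)

setMethod("zScores", "GetisOrdResult", function(object) {
  z <- matrix(NA_real_, object@gridDim[1L], object@gridDim[2L])
  z[cbind(object@stats$row, object@stats$col)] <- object@stats$Z
  z
})

## Cell-centre coordinates (0-based px) honouring the ragged final
## row/column: the last cell's centre is the midpoint of its truncated
## extent.
setMethod("gridCellCentres", "GridCounts", function(object) {
  s <- object@cellSizePx
  w <- object@fieldDimPx[1L]; h <- object@fieldDimPx[2L]
  nc <- ncol(object@counts); nr <- nrow(object@counts)
  cx <- pmin((seq_len(nc) - 0.5) * s, ((seq_len(nc) - 1) * s + w) / 2)
  cy <- pmin((seq_len(nr) - 0.5) * s, ((seq_len(nr) - 1) * s + h) / 2)
  list(x = cx, y = cy)
})

#' @describeIn mamspat-accessors as.data.frame for GetisOrdResult
#' @param x a `GetisOrdResult`.
#' @param row.names,optional,... passed on conventionally; unused.
#' @export
as.data.frame.GetisOrdResult <- function(x, row.names = NULL,
                                         optional = FALSE, ...) x@stats

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@fieldWidthPx, "x", object@fieldHeightPx,
      "px @", format(object@pixelSizeUm, digits = 4), "um/px\n")
  cat("  lobules:", object@nLobules,
      " axis: (", paste(format(object@lobuleAxis, digits = 3),
                        collapse = ", "), ")\n", sep = "")
  cat("  ki67: p0 =", object@ki67P0, " slope =", object@ki67Slope, "\n")
  cat("  macrophage spacing:", object@macrophageSpacingUm, "um (cv",
      object@macrophageSpacingCv, ")\n")
  cat("  stromal mac density c/p:", object@stromalMacDensityCentral, "/",
      object@stromalMacDensityPeripheral, "per mm^2\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth (", object@ageGroup, "): ",
      nrow(object@cells), " cells, ",
      length(object@ductTraces), " ductules, ",
      sum(object@epitheliumMask), " epithelium px\n", sep = "")
  if (nrow(object@cells))
    print(table(object@cells$class))
})

setMethod("show", "StainModel", function(object) {
  cat("StainModel (I0 =",
      paste(format(object@backgroundIntensity, digits = 4), collapse = "/"),
      ")\n")
  m <- round(object@stainMatrix, 4)
  dimnames(m) <- list(c("R", "G", "B"), c("haematoxylin", "DAB"))
  print(m)
  cat("max concentrations:",
      paste(format(object@maxConcentrations, digits = 4), collapse = ", "),
      "\n")
})

setMethod("show", "MaskSet", function(object) {
  cat("MaskSet '", object@fieldId, "': ",
      paste(dim(object@epithelium)[c(2L, 1L)], collapse = " x "), " px, ",
      max(object@ki67Pos), " Ki67+ / ", max(object@ki67Neg),
      " Ki67- nuclei, ", sum(object@epithelium), " epithelium px\n",
      sep = "")
})

setMethod("show", "GridCounts", function(object) {
  cat("GridCounts '", object@phenotype, "': ",
      nrow(object@counts), " x ", ncol(object@counts),
      " cells of ", object@cellSizePx, " px, total ",
      sum(object@counts), " nuclei\n", sep = "")
})

setMethod("show", "GetisOrdResult", function(object) {
  cat("GetisOrdResult: ", paste(object@gridDim, collapse = " x "),
      " grid, d = ", object@dPx, " px", sep = "")
  if (object@nPerm > 0L) cat(", ", object@nPerm, " permutations", sep = "")
  cat("\n")
  z <- object@stats$Z[object@stats$defined]
  cat("  Z range: [", format(min(z), digits = 3), ", ",
      format(max(z), digits = 3), "], ",
      sum(!object@stats$defined), " undefined cells\n", sep = "")
})
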