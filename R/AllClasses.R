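#' @import methods
#' @importFrom stats quantile rnorm runif rbinom rpois sd var median
#'   pnorm pchisq pt qlogis plogis pwilcox setNames complete.cases
#' @importFrom utils combn head tail write.csv read.csv
#' @useDynLib mamspat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Coordinate conventions used throughout:
##  - images and masks are R matrices indexed [row, col] = [y + 1, x + 1];
##  - cell/nucleus coordinates (x_px, y_px) are continuous, 0-based,
##    origin at the top-left pixel corner, x along columns, y along rows;
##  - physical quantities are micrometres (um) or mm^2, converted through
##    pixelSizeUm.

#' Simulation configuration for synthetic H-DAB fields
#'
#' Holds every planted parameter of the synthetic terminal duct lobular
#' unit (TDLU) simulator: field geometry, lobule growth axis, Ki67
#' positivity gradient, intraepithelial macrophage spacing, stromal
#' immune densities, and the Beer-Lambert rendering model (stain matrix,
#' background intensity, optical-density noise).
#'
#' Slots left as `NA` for `ki67P0`, `macrophageSpacingUm` and
#' `tEpiPer100` are filled from the age-group preset at generation time
#' (see [agePreset()]).
#'
#' @slot seed integer root seed; all stage streams derive from it.
#' @slot fieldWidthPx,fieldHeightPx integer field dimensions in pixels.
#' @slot pixelSizeUm numeric, micrometres per pixel.
#' @slot nLobules integer number of lobules placed along the growth axis.
#' @slot lobuleAxis numeric(2) unit growth direction (x, y).
#' @slot ki67P0 baseline Ki67 positivity probability in (0, 1).
#' @slot ki67Slope logistic slope per normalised axis unit.
#' @slot macrophageSpacingUm mean intraepithelial macrophage spacing.
#' @slot macrophageSpacingCv coefficient of variation of spacing jitter.
#' @slot stromalMacDensityCentral,stromalMacDensityPeripheral cells/mm^2.
#' @slot tEpiPer100 intraepithelial T cells per 100 luminal nuclei.
#' @slot stromalTDensity stromal T cells/mm^2.
#' @slot nTls integer number of planted tertiary lymphoid structures.
#' @slot stainMatrix 3x2 optical-density matrix, columns haematoxylin
#'   then DAB, unit norm.
#' @slot backgroundIntensity numeric(3) background intensity I0 per
#'   RGB channel.
#' @slot odNoiseSd Gaussian noise standard deviation in OD units.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  seed = "integer",
  fieldWidthPx = "integer",
  fieldHeightPx = "integer",
  pixelSizeUm = "numeric",
  nLobules = "integer",
  lobuleAxis = "numeric",
  ki67P0 = "numeric",
  ki67Slope = "numeric",
  macrophageSpacingUm = "numeric",
  macrophageSpacingCv = "numeric",
  stromalMacDensityCentral = "numeric",
  stromalMacDensityPeripheral = "numeric",
  tEpiPer100 = "numeric",
  stromalTDensity = "numeric",
  nTls = "integer",
  stainMatrix = "matrix",
  backgroundIntensity = "numeric",
  odNoiseSd = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@fieldWidthPx < 1L || object@fieldHeightPx < 1L)
    msg <- c(msg, "field dimensions must be positive")
  if (!is.finite(object@pixelSizeUm) || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be > 0")
  p0 <- object@ki67P0
  if (!is.na(p0) && (p0 < 0 || p0 > 1))
    msg <- c(msg, "ki67P0 must lie in [0, 1]")
  dens <- c(object@stromalMacDensityCentral,
            object@stromalMacDensityPeripheral, object@stromalTDensity)
  if (any(dens < 0, na.rm = TRUE))
    msg <- c(msg, "densities must be >= 0")
  S <- object@stainMatrix
  if (!all(dim(S) == c(3L, 2L)))
    msg <- c(msg, "stainMatrix must be 3x2")
  else {
    if (any(S < 0)) msg <- c(msg, "stainMatrix entries must be non-negative")
    nrm <- sqrt(colSums(S^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "stainMatrix columns must be unit norm")
  }
  if (length(object@lobuleAxis) != 2L ||
      abs(sqrt(sum(object@lobuleAxis^2)) - 1) > 1e-6)
    msg <- c(msg, "lobuleAxis must be a unit 2-vector")
  if (length(object@backgroundIntensity) != 3L ||
      any(object@backgroundIntensity <= 0))
    msg <- c(msg, "backgroundIntensity must be 3 positive values")
  if (object@odNoiseSd < 0) msg <- c(msg, "odNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Planted ground truth for one synthetic field
#'
#' Container emitted by [generateField()]: one row per planted cell,
#' pixel-perfect compartment masks, lobule geometry with axis
#' coordinates, duct traces carrying intraepithelial macrophage
#' arc-length positions, and an echo of the generating [SimConfig-class].
#'
#' @slot cells data.frame with columns `cellId`, `class`, `x_px`,
#'   `y_px`, `area_px`, `ki67`, `basementContactFraction`, `lobuleId`,
#'   `ductId`, `axisU`.
#' @slot epitheliumMask,stromaMask logical matrices `[row, col]`,
#'   mutually disjoint.
#' @slot lobules data.frame of lobule ellipses (centre, semi-axes, axis
#'   direction, axis extent).
#' @slot ductTraces list; each element describes one ductule: centre,
#'   radius, polyline (`x_px`, `y_px`, `s_um`) and sorted macrophage arc
#'   positions `macArcUm`.
#' @slot config the generating [SimConfig-class].
#' @slot ageGroup `"young"` or `"old"`.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  cells = "data.frame",
  epitheliumMask = "matrix",
  stromaMask = "matrix",
  lobules = "data.frame",
  ductTraces = "list",
  config = "SimConfig",
  ageGroup = "character"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  w <- ncol(object@epitheliumMask); h <- nrow(object@epitheliumMask)
  if (!identical(dim(object@epitheliumMask), dim(object@stromaMask)))
    msg <- c(msg, "epithelium and stroma masks must share dimensions")
  else if (any(object@epitheliumMask & object@stromaMask))
    msg <- c(msg, "epithelium and stroma masks must be disjoint")
  cl <- object@cells
  if (nrow(cl)) {
    if (any(cl$x_px < 0 | cl$x_px >= w | cl$y_px < 0 | cl$y_px >= h))
      msg <- c(msg, "cell centroids must lie inside the field")
  }
  for (d in object@ductTraces)
    if (length(d$macArcUm) > 1L && any(diff(d$macArcUm) < 0))
      msg <- c(msg, "macrophage arc positions must be non-decreasing")
  if (length(msg)) unique(msg) else TRUE
})

#' Macenko stain model
#'
#' A 3x2 optical-density stain matrix (haematoxylin first column, DAB
#' second), the robust per-stain maximum concentrations used for
#' normalisation scaling, and the background intensity I0.
#'
#' @slot stainMatrix 3x2 matrix, unit-norm non-negative columns.
#' @slot maxConcentrations numeric(2), 99th-percentile concentrations.
#' @slot backgroundIntensity numeric(3), I0 per channel.
#' @exportClass StainModel
setClass("StainModel", representation(
  stainMatrix = "matrix",
  maxConcentrations = "numeric",
  backgroundIntensity = "numeric"
))

setValidity("StainModel", function(object) {
  msg <- character()
  S <- object@stainMatrix
  if (!all(dim(S) == c(3L, 2L))) msg <- c(msg, "stainMatrix must be 3x2")
  else if (any(abs(sqrt(colSums(S^2)) - 1) > 1e-6))
    msg <- c(msg, "stainMatrix columns must be unit norm")
  if (length(object@maxConcentrations) != 2L ||
      any(object@maxConcentrations <= 0))
    msg <- c(msg, "maxConcentrations must be 2 positive values")
  if (length(object@backgroundIntensity) != 3L ||
      any(object@backgroundIntensity <= 0))
    msg <- c(msg, "backgroundIntensity must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' Segmentation mask products
#'
#' The two mask products of the segmentation stage: a binary epithelium
#' mask ('epithelium' vs 'background/other') and a three-class nuclei
#' segmentation stored as two mutually exclusive integer label maps
#' (Ki67+ nuclei, Ki67- nuclei; 0 = background/other).
#'
#' @slot epithelium logical matrix.
#' @slot ki67Pos,ki67Neg integer label matrices; a pixel is non-zero in
#'   at most one of the two.
#' @slot fieldId character field identifier.
#' @slot pixelSizeUm micrometres per pixel.
#' @exportClass MaskSet
setClass("MaskSet", representation(
  epithelium = "matrix",
  ki67Pos = "matrix",
  ki67Neg = "matrix",
  fieldId = "character",
  pixelSizeUm = "numeric"
))

setValidity("MaskSet", function(object) {
  msg <- character()
  if (!identical(dim(object@epithelium), dim(object@ki67Pos)) ||
      !identical(dim(object@ki67Pos), dim(object@ki67Neg)))
    msg <- c(msg, "all masks must share field dimensions")
  else if (any(object@ki67Pos > 0 & object@ki67Neg > 0))
    msg <- c(msg, "a pixel may carry at most one nucleus label across phenotypes")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Gridded phenotype counts
#'
#' Nucleus counts per grid cell after discretising centroids onto a
#' regular grid with half-open cells `[k*s, (k+1)*s)`. The ragged final
#' row/column is kept; its cell centres are adjusted accordingly.
#'
#' @slot counts integer matrix `[grid row, grid col]`.
#' @slot cellSizePx grid cell size in pixels.
#' @slot fieldDimPx numeric(2) field (width, height) in pixels.
#' @slot phenotype character tag of the counted phenotype.
#' @exportClass GridCounts
setClass("GridCounts", representation(
  counts = "matrix",
  cellSizePx = "numeric",
  fieldDimPx = "numeric",
  phenotype = "character"
))

setValidity("GridCounts", function(object) {
  msg <- character()
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (object@cellSizePx < 1) msg <- c(msg, "cellSizePx must be >= 1")
  if (length(object@fieldDimPx) != 2L || any(object@fieldDimPx <= 0))
    msg <- c(msg, "fieldDimPx must be 2 positive values")
  if (length(msg)) msg else TRUE
})

#' Getis-Ord GI*(d) result
#'
#' Per-grid-cell self-excluded Getis-Ord ratio G, its conditional
#' randomisation expectation E = W/(n-1) and variance, the z-score, an
#' optional conditional-permutation p-value, and a defined flag (cells
#' whose excluded sum is zero are undefined).
#'
#' @slot stats data.frame with one row per grid cell: `row`, `col`,
#'   `x_px`, `y_px` (cell centre), `count`, `W`, `G`, `E`, `Var`, `Z`,
#'   `defined`, optionally `permP`, `permZ`.
#' @slot gridDim integer(2) grid (rows, cols).
#' @slot cellSizePx grid cell size in pixels.
#' @slot dPx neighbourhood scale d in pixels.
#' @slot nPerm number of conditional permutations used (0 = none).
#' @exportClass GetisOrdResult
setClass("GetisOrdResult", representation(
  stats = "data.frame",
  gridDim = "integer",
  cellSizePx = "numeric",
  dPx = "numeric",
  nPerm = "integer"
))
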