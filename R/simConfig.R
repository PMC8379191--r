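## Derive a reproducible child seed for a named stage from the root
## seed, so individual stages can be re-run without replaying the whole
## stream. Polynomial hash of the stage name folded into 31 bits.
childSeed <- function(seed, stage) {
  h <- 17
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Standard H-DAB stain vectors
#'
#' The widely used published haematoxylin/DAB optical-density pair
#' (haematoxylin (0.65, 0.70, 0.29); DAB (0.27, 0.57, 0.78)), column
#' normalised.
#'
#' @return 3x2 matrix, columns haematoxylin then DAB, unit norm.
#' @export
hdabStainMatrix <- function() {
  S <- cbind(haematoxylin = c(0.65, 0.70, 0.29),
             DAB = c(0.27, 0.57, 0.78))
  sweep(S, 2L, sqrt(colSums(S^2)), "/")
}

#' Construct a simulation configuration
#'
#' Defaults describe a quarter-linear-scale developing-TDLU field:
#' 1580 x 1145 px at 0.9104 um/px covers the same 1.5 mm^2 as a full
#' 6322 x 4581 px field at 0.2276 um/px. Group-dependent parameters
#' (`ki67P0`, `macrophageSpacingUm`, `tEpiPer100`) default to `NA` and
#' are filled from the age-group preset by [generateField()]; explicit
#' values always win.
#'
#' @param seed integer root seed.
#' @param fieldWidthPx,fieldHeightPx field dimensions in pixels.
#' @param pixelSizeUm micrometres per pixel.
#' @param nLobules number of lobules along the growth axis.
#' @param lobuleAxis growth direction; normalised internally.
#' @param ki67P0 baseline Ki67 positivity probability.
#' @param ki67Slope logistic slope per normalised axis unit.
#' @param macrophageSpacingUm mean intraepithelial macrophage spacing.
#' @param macrophageSpacingCv spacing jitter coefficient of variation.
#' @param stromalMacDensityCentral,stromalMacDensityPeripheral
#'   stromal macrophage densities, cells/mm^2.
#' @param tEpiPer100 intraepithelial T cells per 100 luminal nuclei.
#' @param stromalTDensity stromal T cells/mm^2.
#' @param nTls number of planted tertiary lymphoid structures;
#'   defaults to none (TLS occur at whole-slide, not single-field,
#'   frequency - request them explicitly for slide-scale simulations).
#' @param stainMatrix 3x2 OD matrix (haematoxylin, DAB columns).
#' @param backgroundIntensity I0, scalar or per RGB channel.
#' @param odNoiseSd Gaussian OD noise standard deviation.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, nLobules = 1)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      fieldWidthPx = 1580L,
                      fieldHeightPx = 1145L,
                      pixelSizeUm = 0.9104,
                      nLobules = 3L,
                      lobuleAxis = c(1, 0),
                      ki67P0 = NA_real_,
                      ki67Slope = 4,
                      macrophageSpacingUm = NA_real_,
                      macrophageSpacingCv = 0.15,
                      stromalMacDensityCentral = 200,
                      stromalMacDensityPeripheral = 100,
                      tEpiPer100 = NA_real_,
                      stromalTDensity = 60,
                      nTls = 0L,
                      stainMatrix = hdabStainMatrix(),
                      backgroundIntensity = 255,
                      odNoiseSd = 0.02) {
  if (fieldWidthPx < 1 || fieldHeightPx < 1)
    stop("field dimensions must be positive")
  ax <- as.numeric(lobuleAxis)
  n <- sqrt(sum(ax^2))
  if (n == 0) stop("lobuleAxis must be non-zero")
  if (length(backgroundIntensity) == 1L)
    backgroundIntensity <- rep(backgroundIntensity, 3L)
  new("SimConfig",
      seed = as.integer(seed),
      fieldWidthPx = as.integer(fieldWidthPx),
      fieldHeightPx = as.integer(fieldHeightPx),
      pixelSizeUm = pixelSizeUm,
      nLobules = as.integer(nLobules),
      lobuleAxis = ax / n,
      ki67P0 = ki67P0,
      ki67Slope = ki67Slope,
      macrophageSpacingUm = macrophageSpacingUm,
      macrophageSpacingCv = macrophageSpacingCv,
      stromalMacDensityCentral = stromalMacDensityCentral,
      stromalMacDensityPeripheral = stromalMacDensityPeripheral,
      tEpiPer100 = tEpiPer100,
      stromalTDensity = stromalTDensity,
      nTls = as.integer(nTls),
      stainMatrix = stainMatrix,
      backgroundIntensity = backgroundIntensity,
      odNoiseSd = odNoiseSd)
}

#' Age-group parameter presets
#'
#' The two study conditions contrasted throughout: lambs under two
#' months old ("young") and peri-pubertal lambs 5-9.5 months old
#' ("old"). Young animals carry higher epithelial Ki67 positivity and
#' wider intraepithelial macrophage spacing; older animals the
#' converse, with more intraepithelial T cells. Magnitudes are
#' illustrative planted values; the young/old spacing means of 60 and
#' 20 um give a clear, realistic age contrast in the documented
#' direction.
#'
#' @param ageGroup `"young"` or `"old"`.
#' @return named list of preset values for `ki67P0`,
#'   `macrophageSpacingUm` and `tEpiPer100`.
#' @export
agePreset <- function(ageGroup = c("young", "old")) {
  ageGroup <- match.arg(ageGroup)
  if (ageGroup == "young")
    list(ki67P0 = 0.35, macrophageSpacingUm = 60, tEpiPer100 = 1)
  else
    list(ki67P0 = 0.10, macrophageSpacingUm = 20, tEpiPer100 = 3)
}

## Fill NA group-dependent slots from the preset; explicit values win.
applyAgePreset <- function(config, ageGroup) {
  p <- agePreset(ageGroup)
  if (is.na(config@ki67P0)) config@ki67P0 <- p$ki67P0
  if (is.na(config@macrophageSpacingUm))
    config@macrophageSpacingUm <- p$macrophageSpacingUm
  if (is.na(config@tEpiPer100)) config@tEpiPer100 <- p$tEpiPer100
  validObject(config)
  config
}
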