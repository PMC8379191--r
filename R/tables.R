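#' Default distributions for emulated measurement tables
#'
#' Per-group generative settings for each measure of the per-animal
#' measurement table: mean and standard deviation of the animal-level
#' distribution, plus the number of within-animal replicates for the
#' pooled measures (inter-macrophage distances). Values mirror the
#' synthetic field presets: higher Ki67 and wider macrophage spacing
#' in the young group, more intraepithelial T cells and a central >
#' peripheral stromal macrophage gradient in both.
#'
#' @return nested list `measure -> group -> c(mean, sd)` plus
#'   replicate counts.
#' @export
measurementDefaults <- function() {
  list(
    ki67_epithelial_ratio = list(
      young = c(mean = 0.45, sd = 0.12), old = c(mean = 0.12, sd = 0.05),
      perAnimal = 1L, min = 0.005),
    inter_macrophage_distance_um = list(
      young = c(mean = 60, sd = 9), old = c(mean = 20, sd = 3),
      perAnimal = 30L, min = 1),
    stromal_mac_density_central = list(
      young = c(mean = 200, sd = 40), old = c(mean = 200, sd = 40),
      perAnimal = 1L, min = 0),
    stromal_mac_density_peripheral = list(
      young = c(mean = 100, sd = 30), old = c(mean = 100, sd = 30),
      perAnimal = 1L, min = 0),
    epithelial_t_per100 = list(
      young = c(mean = 1, sd = 0.4), old = c(mean = 3, sd = 1),
      perAnimal = 1L, min = 0),
    stromal_t_density = list(
      young = c(mean = 60, sd = 15), old = c(mean = 60, sd = 15),
      perAnimal = 1L, min = 0),
    tls_density_mm2 = list(
      young = c(mean = 0.05, sd = 0.03), old = c(mean = 0.05, sd = 0.03),
      perAnimal = 1L, min = 0))
}

#' Emulate the per-animal measurement table
#'
#' Draws per-animal rows for every measure from configured group
#' distributions, reproducing the statistical structure of a
#' per-animal measurement workbook (one value per animal per measure,
#' except the
#' inter-macrophage distances which pool many gaps per animal, and the
#' paired central/peripheral stromal macrophage densities which share
#' a per-animal random effect). The result feeds [compareGroups()]
#' directly and is CSV-serialisable.
#'
#' @param nAnimalsPerGroup integer (shared) or named vector
#'   `c(young = , old = )`; each group needs at least 2 animals. The
#'   default 7 + 6 gives a typical 13-lamb design.
#' @param seed RNG seed.
#' @param params distribution settings, see [measurementDefaults()].
#'   Setting every `sd` to 0 yields a degenerate all-equal table;
#'   giving both groups identical settings yields a null table.
#' @return data.frame with columns `animalId`, `ageGroup`,
#'   `ageMonths`, `measure`, `value`.
#' @export
emulateMeasurementTables <- function(nAnimalsPerGroup = c(young = 7L, old = 6L),
                                     seed = 1L,
                                     params = measurementDefaults()) {
  if (length(nAnimalsPerGroup) == 1L)
    nAnimalsPerGroup <- c(young = nAnimalsPerGroup, old = nAnimalsPerGroup)
  if (any(nAnimalsPerGroup < 2L))
    stop("at least 2 animals per group are required for group tests")
  groups <- rep(c("young", "old"), nAnimalsPerGroup[c("young", "old")])
  ids <- sprintf("lamb%02d", seq_along(groups))
  rows <- list()
  withSeed(seed, {
    ageMonths <- ifelse(groups == "young", runif(length(groups), 0.1, 2),
                        runif(length(groups), 5, 9.5))
    ## shared per-animal effect correlating central/peripheral densities
    animalEff <- rnorm(length(groups), 0, 1)
    for (mname in names(params)) {
      pp <- params[[mname]]
      for (ai in seq_along(ids)) {
        gp <- pp[[groups[ai]]]
        nrep <- pp$perAnimal
        if (mname %in% c("stromal_mac_density_central",
                         "stromal_mac_density_peripheral")) {
          val <- gp["mean"] + animalEff[ai] * gp["sd"] * 0.6 +
            rnorm(nrep, 0, gp["sd"] * 0.8)
        } else if (nrep > 1L) {
          animalMean <- rnorm(1, gp["mean"], gp["sd"] * 0.5)
          val <- rnorm(nrep, animalMean, gp["sd"])
        } else {
          val <- rnorm(nrep, gp["mean"], gp["sd"])
        }
        val <- pmax(pp$min, val)
        rows[[length(rows) + 1L]] <- data.frame(
          animalId = ids[ai], ageGroup = groups[ai],
          ageMonths = ageMonths[ai], measure = mname, value = val)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
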