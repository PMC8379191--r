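## End-to-end evaluation runs: each function recomputes one of the
## package's headline validation quantities from scratch (simulate ->
## analyse -> measure against the planted truth). They back both the
## validation test suite and scripts/acceptance.R.

#' Getis-Ord three-cell worked example
#'
#' Discretises the counts (2, 1, 0) on a linear three-cell grid with a
#' neighbourhood spanning adjacent cells only and returns the first
#' cell's statistic next to its exhaustive conditional-permutation
#' moments.
#'
#' @return list with `G`, `E`, `Var`, `Z`, `permMean`, `permVar`.
#' @export
evaluateGetisOrdExample <- function() {
  cent <- data.frame(x_px = c(5, 5, 15), y_px = c(5, 5, 5),
                     phenotype = "p")
  g <- gridDiscretise(cent, c(30, 10), 10, "p")
  go <- as.data.frame(getisOrd(g, 15))
  ex <- as.data.frame(permutationNull(g, 15, exhaustive = TRUE))
  list(G = go$G[1], E = go$E[1], Var = go$Var[1], Z = go$Z[1],
       permMean = ex$permMean[1], permVar = ex$permVar[1])
}

#' Moment versus permutation z-score agreement
#'
#' Random Poisson grids; for each, the closed-form conditional
#' randomisation z is compared with the z of a sampled conditional
#' permutation null.
#'
#' @param nGrids number of random grids.
#' @param dim grid side length.
#' @param lambda Poisson mean per cell.
#' @param nPerm permutations per cell.
#' @param dCells neighbourhood scale in cell units.
#' @param seed RNG seed.
#' @return list with `meanAbsDz` and `nCells`.
#' @export
evaluateMomentVsPermutation <- function(nGrids = 50, dim = 20,
                                        lambda = 5, nPerm = 9999,
                                        dCells = 5, seed = 1) {
  dzs <- withSeed(seed, {
    vapply(seq_len(nGrids), function(b) {
      counts <- matrix(rpois(dim * dim, lambda), dim, dim)
      cent <- data.frame(
        x_px = rep(rep((seq_len(dim) - 0.5) * 10, times = dim),
                   as.integer(t(counts))),
        y_px = rep(rep((seq_len(dim) - 0.5) * 10, each = dim),
                   as.integer(t(counts))),
        phenotype = "p")
      g <- gridDiscretise(cent, c(dim * 10, dim * 10), 10, "p")
      pn <- as.data.frame(permutationNull(g, dCells * 10, nPerm,
                                          seed = seed + b))
      mean(abs(pn$Z[pn$defined] - pn$permZ[pn$defined]))
    }, numeric(1))
  })
  list(meanAbsDz = mean(dzs), nCells = dim * dim * nGrids)
}

#' Hotspot calibration under complete spatial randomness
#'
#' Uniformly scattered centroids are gridded and the fraction of cells
#' with Z at or above the threshold is measured per field. Fields are
#' the independent replicates: the summary reports the mean fraction
#' with its standard error across fields (GI* neighbourhoods overlap,
#' so cells within a field are correlated).
#'
#' @param nFields number of CSR fields.
#' @param nPoints centroids per field.
#' @param fieldW square field side (px).
#' @param cellSize grid cell size (px).
#' @param dPx neighbourhood scale (px).
#' @param z threshold (one-sided high).
#' @param seed RNG seed.
#' @return list with `fraction` (pooled), `meanPerField`, `sePerField`,
#'   `nominal`, `nFields`.
#' @export
evaluateCsrCalibration <- function(nFields = 200, nPoints = 8000,
                                   fieldW = 200, cellSize = 10,
                                   dPx = 50, z = 1.96, seed = 1) {
  res <- withSeed(seed, {
    vapply(seq_len(nFields), function(b) {
      cent <- data.frame(x_px = runif(nPoints, 0, fieldW),
                         y_px = runif(nPoints, 0, fieldW),
                         phenotype = "p")
      g <- gridDiscretise(cent, c(fieldW, fieldW), cellSize, "p")
      df <- as.data.frame(getisOrd(g, dPx))
      c(sum(df$defined & df$Z >= z), sum(df$defined))
    }, numeric(2))
  })
  frac <- res[1, ] / res[2, ]
  list(fraction = sum(res[1, ]) / sum(res[2, ]),
       meanPerField = mean(frac),
       sePerField = sd(frac) / sqrt(nFields),
       nominal = pnorm(z, lower.tail = FALSE), nFields = nFields)
}

#' Polarisation of Ki67 hotspots along the growth axis
#'
#' Simulates default young fields at the given logistic slope, maps
#' Ki67+ epithelial centroids to hotspot grids and pools the
#' polarisation index (fraction of hotspot cells on the leading half).
#'
#' @param nFields fields to simulate.
#' @param slope logistic axis slope (`NULL` keeps the young preset).
#' @param seed base seed; field b uses `seed * 1000 + b`.
#' @param cellSizePx,dPx analysis grid (defaults match d = 250 px at
#'   full scan scale).
#' @return list with `index` (pooled), `nHotspot`, `nLeading`,
#'   `perField` indices, `binomP` (one-sided, pooled).
#' @export
evaluatePolarisation <- function(nFields = 6, slope = 4, seed = 1,
                                 cellSizePx = 12.5, dPx = 62.5) {
  idx <- matrix(0, 3, nFields)
  for (b in seq_len(nFields)) {
    cfg <- simConfig(seed = seed * 1000 + b, ki67Slope = slope)
    gt <- generateField(cfg, "young")
    cl <- cells(gt)
    epiPos <- cl[cl$ki67 & cl$class %in% c("luminal", "basal"), ]
    epiPos$phenotype <- "ki67_pos"
    g <- gridDiscretise(epiPos,
                        c(cfg@fieldWidthPx, cfg@fieldHeightPx),
                        cellSizePx, "ki67_pos")
    go <- getisOrd(g, dPx)
    hot <- hotspotMask(go, 1.96)
    p <- polarisationIndex(hot, gridAxisCoord(go, gt@lobules))
    idx[, b] <- c(p$index, p$nHotspot, p$nLeading)
  }
  nHot <- sum(idx[2, ]); nLead <- sum(idx[3, ])
  list(index = nLead / nHot, nHotspot = nHot, nLeading = nLead,
       perField = idx[1, ],
       binomP = stats::binom.test(nLead, nHot, 0.5,
                                  alternative = "greater")$p.value)
}

#' Stain-vector recovery and normalisation idempotence
#'
#' Renders a default young field with planted stain vectors at the
#' given OD noise, re-estimates the stain matrix and reports the
#' angular errors; separately checks that normalising a noise-free
#' render to its own model is the identity.
#'
#' @param seed RNG seed.
#' @param noiseSd OD noise for the recovery check.
#' @return list with `angleHaem`, `angleDab` (degrees), `maxAbsDev`
#'   (intensity units, idempotence check).
#' @export
evaluateStainRecovery <- function(seed = 1, noiseSd = 0.02) {
  gt <- generateField(simConfig(seed = seed, odNoiseSd = noiseSd),
                      "young")
  f <- renderField(gt)
  sm <- estimateStainMatrix(f)
  ang <- stainAngle(stainMatrix(sm), hdabStainMatrix())

  gt0 <- generateField(simConfig(seed = seed, odNoiseSd = 0,
                                 fieldWidthPx = 700L,
                                 fieldHeightPx = 500L, nLobules = 1L),
                       "young")
  f0 <- renderField(gt0)
  sm0 <- estimateStainMatrix(f0, smoothSigma = 0)
  out <- normalizeToReference(rgbArray(f0), sm0, sm0)
  list(angleHaem = ang[1L], angleDab = ang[2L],
       maxAbsDev = max(abs(out - rgbArray(f0))))
}

#' Segmentation recovery against planted truth
#'
#' Full chain on one default young field: render, stain estimation,
#' nuclei and epithelium segmentation; reports the nucleus count error,
#' the epithelial Ki67 pixel-ratio error against the planted label
#' masks (Ki67- nuclei are all non-DAB nuclei, mirroring the 3-class
#' mask contract), and the epithelium Dice.
#'
#' @param seed RNG seed.
#' @return list with `countRelErrPct`, `ratioRelErrPct`, `dice`,
#'   `nNuclei`.
#' @export
evaluateSegmentationRecovery <- function(seed = 1) {
  gt <- generateField(simConfig(seed = seed), "young")
  f <- renderField(gt)
  sm <- estimateStainMatrix(f)
  ms <- segmentEpithelium(segmentNuclei(f, sm))
  cl <- cells(gt)
  lab <- labelMasks(f)
  truth <- epitheliumMask(gt)
  tp <- sum(lab$ki67Pos > 0 & truth)
  tn <- sum(lab$nuclei > 0 & !(lab$ki67Pos > 0) & truth)
  kr <- ki67EpithelialRatio(ms)
  nTot <- max(ki67NegLabels(ms))
  list(countRelErrPct = (nTot / nrow(cl) - 1) * 100,
       ratioRelErrPct = (kr$ratio / (tp / tn) - 1) * 100,
       dice = 2 * sum(epitheliumMask(ms) & truth) /
         (sum(epitheliumMask(ms)) + sum(truth)),
       nNuclei = nrow(cl))
}

#' Macrophage spacing recovery and the age-group contrast
#'
#' Pools periodic-run inter-macrophage distances over simulated fields
#' per age preset and compares the recovered means with the planted
#' spacings; additionally repeats the 13-animal group comparison over
#' independent seeds and reports how often the two-tailed Mann-Whitney
#' falls below p = 0.001.
#'
#' @param nFieldsYoung,nFieldsOld fields pooled per preset (the
#'   defaults pool several hundred gaps per preset).
#' @param nSeeds replicate group comparisons.
#' @param seed base seed.
#' @return list with `relErrYoungPct`, `relErrOldPct`, `nGapsYoung`,
#'   `nGapsOld`, `fracSignif`, `meanYoung`, `meanOld`.
#' @export
evaluateSpacingRecovery <- function(nFieldsYoung = 32, nFieldsOld = 3,
                                    nSeeds = 20, seed = 1) {
  young <- unlist(lapply(seq_len(nFieldsYoung), function(b)
    fieldMacrophageDistances(
      generateField(simConfig(seed = seed * 500 + b), "young"))))
  old <- unlist(lapply(seq_len(nFieldsOld), function(b)
    fieldMacrophageDistances(
      generateField(simConfig(seed = seed * 500 + b), "old"))))
  sig <- vapply(seq_len(nSeeds), function(b) {
    tab <- emulateMeasurementTables(seed = seed * 900 + b)
    cmp <- compareGroups(tab, "inter_macrophage_distance_um")
    dir <- cmp$groups$mean[cmp$groups$group == "young"] >
      cmp$groups$mean[cmp$groups$group == "old"]
    cmp$p.value < 0.001 && dir
  }, logical(1))
  list(relErrYoungPct = (mean(young) / 60 - 1) * 100,
       relErrOldPct = (mean(old) / 20 - 1) * 100,
       nGapsYoung = length(young), nGapsOld = length(old),
       fracSignif = mean(sig),
       meanYoung = mean(young), meanOld = mean(old))
}
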