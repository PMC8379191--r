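#' Default pipeline configuration
#'
#' Flat blocks per stage. Physical defaults follow the analysis
#' conventions used throughout: Getis-Ord scale d = 250 px at the full
#' 0.2276 um/px scan scale (56.9 um), grid cells of 50 px (11.38 um) so
#' d spans five cells, z threshold 1.96, count boxes 400 x 230 um,
#' periodicity gap CV tolerance 0.30.
#'
#' @return nested named list of defaults.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(
      fieldWidthPx = 1580L, fieldHeightPx = 1145L,
      pixelSizeUm = 0.9104, nLobules = 3L, ageGroups = c("young", "old"),
      odNoiseSd = 0.02),
    normalize = list(enabled = TRUE),
    segment = list(enabled = TRUE),
    hotspot = list(enabled = TRUE, cellSizeUm = 11.38, dUm = 56.9,
                   zThreshold = 1.96, permutations = 0L,
                   phenotype = "ki67_pos"),
    immune = list(enabled = TRUE, nBoxesPerClass = 4L,
                  boxWidthUm = 400, boxHeightUm = 230,
                  cvTol = 0.30, minRunLength = 4L, clusterGapUm = 8),
    stats = list(enabled = TRUE, nAnimalsPerGroup = c(young = 7L, old = 6L))
  )
}

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown configuration key: ",
           if (nzchar(path)) paste0(path, ".", key) else key)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]],
                                     paste0(path, if (nzchar(path)) ".", key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), rejects unknown keys, fills
#' defaults, checks parameter domains and resolves physical units to
#' pixels through the simulated pixel size (e.g. d given in um becomes
#' `dUm / pixelSizeUm` pixels).
#'
#' @param config path to a YAML file, a list, or `NULL` for defaults.
#' @return normalised configuration list with derived `hotspot$dPx`
#'   and `hotspot$cellSizePx`.
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  px <- cfg$simulate$pixelSizeUm
  if (px <= 0) stop("simulate.pixelSizeUm must be > 0")
  if (cfg$simulate$fieldWidthPx < 1 || cfg$simulate$fieldHeightPx < 1)
    stop("simulate field dimensions must be positive")
  if (cfg$simulate$odNoiseSd < 0) stop("simulate.odNoiseSd must be >= 0")
  if (cfg$hotspot$zThreshold < 0) stop("hotspot.zThreshold must be >= 0")
  if (cfg$immune$boxWidthUm <= 0 || cfg$immune$boxHeightUm <= 0)
    stop("immune box dimensions must be positive")
  if (any(unlist(cfg$stats$nAnimalsPerGroup) < 2))
    stop("stats.nAnimalsPerGroup must be >= 2")
  cfg$hotspot$dPx <- cfg$hotspot$dUm / px
  cfg$hotspot$cellSizePx <- cfg$hotspot$cellSizeUm / px
  cfg
}

## deterministic 32-bit polynomial hash of the serialised configuration
configHash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", h)
}

writeMaskTiff <- function(mask, path) {
  m <- mask
  if (is.logical(m)) m <- m * 1
  tiff::writeTIFF(m / max(1, max(m)), path, bits.per.sample = 16L)
  invisible(path)
}

writeFieldPng <- function(field, path) {
  r <- field@rgb / 255
  r[r > 1] <- 1; r[r < 0] <- 0
  png::writePNG(r, path)
  invisible(path)
}

#' Run the full analysis pipeline on synthetic fields
#'
#' Executes simulate, render, normalise, segment, Ki67 ratio, hotspot,
#' immune quantification and group statistics in order, honouring the
#' stage toggles, and writes every artefact plus a manifest (config
#' hash, seed, stage list) into `outDir`. Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config see [validateConfig()].
#' @param outDir output directory (created if missing).
#' @return invisibly, a list of in-memory results per stage.
#' @export
runPipeline <- function(config = NULL, outDir = tempfile("mamspat-run-")) {
  cfg <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = cfg)
  px <- cfg$simulate$pixelSizeUm

  if (cfg$hotspot$enabled && !cfg$segment$enabled)
    stop("stage dependency: hotspot requires segment (it consumes the ",
         "centroid table); enable segment or disable hotspot")

  measurements <- list()
  for (age in cfg$simulate$ageGroups) {
    sc <- simConfig(seed = cfg$seed,
                    fieldWidthPx = cfg$simulate$fieldWidthPx,
                    fieldHeightPx = cfg$simulate$fieldHeightPx,
                    pixelSizeUm = px,
                    nLobules = cfg$simulate$nLobules,
                    odNoiseSd = cfg$simulate$odNoiseSd)
    gt <- generateField(sc, age)
    field <- renderField(gt, marker = "ki67")
    write.csv(cells(gt), file.path(outDir, paste0("cells-", age, ".csv")),
              row.names = FALSE)
    writeFieldPng(field, file.path(outDir, paste0("field-", age, ".png")))
    writeMaskTiff(epitheliumMask(gt),
                  file.path(outDir, paste0("epithelium-truth-", age, ".tif")))

    stain <- estimateStainMatrix(field)
    if (cfg$normalize$enabled) {
      field <- normalizeToReference(field, stain, stain)
      writeStainModel(stain, file.path(outDir, paste0("stain-", age, ".yaml")))
    }

    masks <- NULL
    if (cfg$segment$enabled) {
      masks <- segmentNuclei(field, stain)
      masks <- segmentEpithelium(masks)
      writeMaskTiff(masks@epithelium,
                    file.path(outDir, paste0("epithelium-", age, ".tif")))
      writeMaskTiff(masks@ki67Pos,
                    file.path(outDir, paste0("ki67pos-", age, ".tif")))
      writeMaskTiff(masks@ki67Neg,
                    file.path(outDir, paste0("ki67neg-", age, ".tif")))
      cent <- extractCentroids(masks)
      write.csv(cent, file.path(outDir, paste0("centroids-", age, ".csv")),
                row.names = FALSE)
      kr <- ki67EpithelialRatio(masks)
      measurements[[length(measurements) + 1L]] <- data.frame(
        ageGroup = age, measure = "ki67_epithelial_ratio",
        value = kr$ratio, units = "ratio")

      if (cfg$hotspot$enabled) {
        epiPos <- cent[cent$phenotype == "ki67_pos" & cent$epithelial, ]
        grid <- gridDiscretise(epiPos,
                               c(ncol(masks@epithelium), nrow(masks@epithelium)),
                               cfg$hotspot$cellSizePx)
        go <- getisOrd(grid, cfg$hotspot$dPx)
        if (cfg$hotspot$permutations > 0L)
          go <- permutationNull(grid, cfg$hotspot$dPx,
                                cfg$hotspot$permutations, cfg$seed)
        write.csv(as.data.frame(go),
                  file.path(outDir, paste0("getisord-", age, ".csv")),
                  row.names = FALSE)
        hot <- hotspotMask(go, cfg$hotspot$zThreshold)
        pol <- polarisationIndex(hot, gridAxisCoord(go, gt@lobules))
        measurements[[length(measurements) + 1L]] <- data.frame(
          ageGroup = age, measure = "polarisation_index",
          value = pol$index, units = "fraction")
      }
    }

    if (cfg$immune$enabled) {
      dists <- fieldMacrophageDistances(gt, cfg$immune$cvTol,
                                        cfg$immune$minRunLength,
                                        cfg$immune$clusterGapUm)
      if (length(dists))
        measurements[[length(measurements) + 1L]] <- data.frame(
          ageGroup = age, measure = "inter_macrophage_distance_um",
          value = dists, units = "um")
      paren <- epitheliumMask(gt) | stromaMask(gt)
      boxes <- tryCatch(
        placeCountBoxes(paren, px, 2L * cfg$immune$nBoxesPerClass,
                        cfg$immune$boxWidthUm, cfg$immune$boxHeightUm,
                        seed = childSeed(cfg$seed, paste0("boxes-", age))),
        error = function(e) NULL)
      if (!is.null(boxes)) {
        boxes$location <- vapply(seq_len(nrow(boxes)), function(k)
          classifyBoxLocation(boxes[k, ], paren, px), character(1L))
        bm <- do.call(rbind, lapply(seq_len(nrow(boxes)), function(k)
          measureCountBox(boxes[k, ], gt)))
        bm$location <- boxes$location
        write.csv(cbind(boxes[, c("boxId", "x0_px", "y0_px", "location")],
                        bm[, -1L]),
                  file.path(outDir, paste0("boxes-", age, ".csv")),
                  row.names = FALSE)
        for (loc in c("central", "peripheral")) {
          sel <- bm$location == loc & is.finite(bm$stromalMacDensity)
          if (any(sel))
            measurements[[length(measurements) + 1L]] <- data.frame(
              ageGroup = age,
              measure = paste0("stromal_mac_density_", loc),
              value = mean(bm$stromalMacDensity[sel]), units = "cells/mm2")
        }
      }
      cl <- cells(gt)
      tissueMm2 <- sum(paren) * (px / 1000)^2
      tls <- detectTLS(cl[cl$class == "b_cell", ],
                       cl[cl$class %in% c("t_cell_stromal",
                                          "t_cell_epithelial"), ],
                       tissueMm2, px)
      measurements[[length(measurements) + 1L]] <- data.frame(
        ageGroup = age, measure = "tls_density_mm2",
        value = tls$densityMm2, units = "per mm2")
    }
    res[[paste0("field_", age)]] <- list(gt = gt, masks = masks)
  }

  meas <- do.call(rbind, measurements)
  write.csv(meas, file.path(outDir, "measurements.csv"), row.names = FALSE)
  res$measurements <- meas

  if (cfg$stats$enabled) {
    tab <- emulateMeasurementTables(
      nAnimalsPerGroup = unlist(cfg$stats$nAnimalsPerGroup),
      seed = childSeed(cfg$seed, "tables"))
    write.csv(tab, file.path(outDir, "animal_table.csv"), row.names = FALSE)
    report <- do.call(rbind, lapply(unique(tab$measure), function(m) {
      cmp <- compareGroups(tab, m)
      data.frame(measure = m, test = cmp$test, statistic = cmp$statistic,
                 p.value = cmp$p.value,
                 mean_young = cmp$groups$mean[cmp$groups$group == "young"],
                 mean_old = cmp$groups$mean[cmp$groups$group == "old"])
    }))
    write.csv(report, file.path(outDir, "stats_report.csv"),
              row.names = FALSE)
    res$statsReport <- report
  }

  jsonlite::write_json(
    list(configHash = configHash(cfg), seed = cfg$seed,
         stages = names(Filter(function(s) isTRUE(s$enabled),
                               cfg[c("normalize", "segment", "hotspot",
                                     "immune", "stats")])),
         package = "mamspat",
         version = as.character(utils::packageVersion("mamspat"))),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  invisible(res)
}
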