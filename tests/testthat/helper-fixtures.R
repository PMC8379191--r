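## Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

## A default-scale young field with its render and estimated stains;
## the most expensive shared fixture.
youngField <- function() {
  if (is.null(.fixtures$young)) {
    gt <- generateField(simConfig(seed = 101), "young")
    f <- renderField(gt)
    .fixtures$young <- list(gt = gt, field = f,
                            stain = estimateStainMatrix(f))
  }
  .fixtures$young
}

## Fabricate a GroundTruth with hand-placed cells on an empty canvas.
makeTruth <- function(cells, w = 60L, h = 50L, pixelSizeUm = 1,
                      seed = 1L, odNoiseSd = 0) {
  cfg <- simConfig(seed = seed, fieldWidthPx = w, fieldHeightPx = h,
                   pixelSizeUm = pixelSizeUm, nLobules = 0L,
                   ki67P0 = 0.5, macrophageSpacingUm = 60,
                   tEpiPer100 = 1, odNoiseSd = odNoiseSd)
  new("GroundTruth", cells = cells,
      epitheliumMask = matrix(FALSE, h, w),
      stromaMask = matrix(FALSE, h, w),
      lobules = data.frame(lobuleId = integer(), cx = numeric(),
                           cy = numeric(), a = numeric(), b = numeric(),
                           axisX = numeric(), axisY = numeric()),
      ductTraces = list(), config = cfg, ageGroup = "young")
}

cellRows <- function(class, x, y, areaPx, ki67 = FALSE, bcf = 0,
                     u = NA_real_) {
  n <- length(x)
  data.frame(cellId = seq_len(n), class = rep(class, length.out = n),
             x_px = x, y_px = y,
             area_px = rep(areaPx, length.out = n),
             ki67 = rep(ki67, length.out = n),
             basementContactFraction = rep(bcf, length.out = n),
             lobuleId = rep(NA_integer_, n),
             ductId = rep(NA_integer_, n),
             axisU = rep(u, length.out = n),
             stringsAsFactors = FALSE)
}

## Poisson-count grid as GridCounts plus the matching centroid table.
poissonGrid <- function(nr, nc, lambda, cellSize = 10) {
  counts <- matrix(rpois(nr * nc, lambda), nr, nc)
  reps <- as.integer(t(counts))  # row-major over (row, col)
  cent <- data.frame(
    x_px = rep(rep((seq_len(nc) - 0.5) * cellSize, times = nr), reps),
    y_px = rep(rep((seq_len(nr) - 0.5) * cellSize, each = nc), reps),
    phenotype = "p")
  gridDiscretise(cent, c(nc * cellSize, nr * cellSize), cellSize, "p")
}

diceOf <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
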