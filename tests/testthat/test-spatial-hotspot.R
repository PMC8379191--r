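test_that("grid discretisation uses half-open cells and conserves counts", {
  ## empty input: all-zero grid with a warning
  none <- data.frame(x_px = numeric(), y_px = numeric(),
                     phenotype = character())
  expect_warning(g0 <- gridDiscretise(none, c(100, 100), 10, "p"),
                 "all-zero")
  expect_equal(sum(gridCounts(g0)), 0)

  ## boundary centroid falls in the upper cell
  cent <- data.frame(x_px = 10, y_px = 10, phenotype = "p")
  g <- gridDiscretise(cent, c(30, 30), 10, "p")
  expect_equal(gridCounts(g)[2, 2], 1L)
  expect_equal(gridCounts(g)[1, 1], 0L)

  ## conservation for uniform scatter, ragged grid kept
  set.seed(4)
  cent <- data.frame(x_px = runif(1000, 0, 105), y_px = runif(1000, 0, 97),
                     phenotype = "p")
  g <- gridDiscretise(cent, c(105, 97), 10, "p")
  expect_equal(dim(gridCounts(g)), c(10L, 11L))
  expect_equal(sum(gridCounts(g)), 1000)
  ## ragged final centres sit at the truncated cell midpoint
  ctr <- gridCellCentres(g)
  expect_equal(ctr$x[11], (100 + 105) / 2)
  expect_equal(ctr$y[10], (90 + 97) / 2)
})

test_that("the three-cell worked example matches exhaustive enumeration", {
  cent <- data.frame(x_px = c(5, 5, 15), y_px = c(5, 5, 5),
                     phenotype = "p")
  g <- gridDiscretise(cent, c(30, 10), 10, "p")
  expect_equal(as.integer(gridCounts(g)), c(2L, 1L, 0L))
  go <- as.data.frame(getisOrd(g, 15))
  expect_equal(go$G[1], 1)
  expect_equal(go$E[1], 0.5)
  expect_equal(go$Var[1], 0.25)
  expect_equal(go$Z[1], 1)
  ## exhaustive conditional permutation reproduces the moments exactly
  ex <- as.data.frame(permutationNull(g, 15, exhaustive = TRUE))
  expect_equal(ex$permMean, go$E)
  expect_equal(ex$permVar, go$Var)
  expect_equal(ex$permZ, go$Z)
})

test_that("degenerate grids follow the stated conventions", {
  ## constant grid: no spatial variation, Z = 0 everywhere
  cent <- expand.grid(x_px = (1:4) * 10 - 5, y_px = (1:4) * 10 - 5)
  cent$phenotype <- "p"
  g <- gridDiscretise(cent, c(40, 40), 10, "p")
  go <- as.data.frame(getisOrd(g, 15))
  expect_true(all(go$Z == 0))
  ## all zero counts: error
  g0 <- suppressWarnings(gridDiscretise(
    data.frame(x_px = numeric(), y_px = numeric(),
               phenotype = character()), c(40, 40), 10, "p"))
  expect_error(getisOrd(g0, 15), "zero")
  expect_error(permutationNull(g, 15, nPerm = 0), "at least 1")
})

test_that("moment formula matches sampled conditional permutation", {
  set.seed(31)
  for (nr in c(5, 12, 20)) {
    g <- poissonGrid(nr, nr, lambda = 5)
    pn <- as.data.frame(permutationNull(g, 3.2 * 10, nPerm = 1999,
                                        seed = 5))
    ok <- pn$defined
    expect_lt(mean(abs(pn$Z[ok] - pn$permZ[ok])), 0.06)
    ## empirical mean of G converges on E = W/(n-1)
    expect_lt(max(abs(pn$permMean[ok] - pn$E[ok])), 0.05)
  }
})

test_that("Z field is translation invariant and monotone in local counts", {
  set.seed(8)
  cent <- data.frame(x_px = runif(400, 0, 80), y_px = runif(400, 0, 80),
                     phenotype = "p")
  g1 <- gridDiscretise(cent, c(120, 120), 10, "p")
  shifted <- transform(cent, x_px = x_px + 20, y_px = y_px + 30)
  g2 <- gridDiscretise(shifted, c(120, 120), 10, "p")
  z1 <- zScores(getisOrd(g1, 25))
  z2 <- zScores(getisOrd(g2, 25))
  ## compare cells whose d-neighbourhood is untruncated in both grids
  expect_equal(z1[3:6, 3:7], z2[3:6 + 3, 3:7 + 2])

  ## monotonicity: adding counts to one cell never lowers its Z
  zs <- sapply(c(0, 5, 20, 60), function(extra) {
    gg <- g1
    cc <- gridCounts(gg); cc[5, 5] <- cc[5, 5] + as.integer(extra)
    gg@counts <- cc
    as.data.frame(getisOrd(gg, 25))$Z[(5 - 1) * nrow(cc) + 5]
  })
  expect_true(all(diff(zs) >= 0))
})

test_that("hotspot mask and polarisation index behave at the edges", {
  cent <- expand.grid(x_px = (1:5) * 10 - 5, y_px = (1:5) * 10 - 5)
  cent$phenotype <- "p"
  g <- gridDiscretise(cent, c(50, 50), 10, "p")
  go <- getisOrd(g, 15)
  expect_equal(sum(hotspotMask(go, 1.96)), 0)      # all Z zero
  expect_equal(sum(hotspotMask(go, -Inf)), 25)     # all defined cells
  u <- matrix(runif(25), 5, 5)
  expect_warning(p <- polarisationIndex(hotspotMask(go, 1.96), u),
                 "undefined")
  expect_true(is.na(p$index))
  ## all hotspots on the leading half
  m <- matrix(FALSE, 5, 5); m[, 4:5] <- TRUE
  u2 <- matrix(rep(seq(0.1, 0.9, length.out = 5), each = 5), 5, 5)
  expect_equal(polarisationIndex(m, u2)$index, 1)
})

test_that("hotspots of a planted gradient sit at the leading edge", {
  gt <- youngField()$gt
  cl <- cells(gt)
  epiPos <- cl[cl$ki67 & cl$class %in% c("luminal", "basal"), ]
  epiPos$phenotype <- "ki67_pos"
  g <- gridDiscretise(epiPos, c(1580, 1145), 12.5, "ki67_pos")
  go <- getisOrd(g, 62.5)
  hot <- hotspotMask(go, 1.96)
  pol <- polarisationIndex(hot, gridAxisCoord(go, gt@lobules))
  expect_gt(pol$nHotspot, 100)
  expect_gt(pol$index, 0.5)
})
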