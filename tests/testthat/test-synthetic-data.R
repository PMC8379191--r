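test_that("generation is deterministic and honours its invariants", {
  cfg <- simConfig(seed = 7, fieldWidthPx = 700L, fieldHeightPx = 500L,
                   nLobules = 1L)
  gt1 <- generateField(cfg, "young")
  gt2 <- generateField(cfg, "young")
  expect_identical(cells(gt1), cells(gt2))
  expect_identical(epitheliumMask(gt1), epitheliumMask(gt2))

  cl <- cells(gt1)
  expect_true(all(cl$x_px >= 0 & cl$x_px < 700))
  expect_true(all(cl$y_px >= 0 & cl$y_px < 500))
  expect_false(any(epitheliumMask(gt1) & stromaMask(gt1)))
  for (d in ductTraces(gt1))
    expect_true(all(diff(d$macArcUm) >= 0))
  ## all main cell classes present under positive densities
  expect_true(all(c("luminal", "basal", "macrophage_intraepithelial",
                    "macrophage_stromal", "t_cell_stromal") %in%
                    cl$class))
  ## a different age group gives a different field
  gt3 <- generateField(cfg, "old")
  expect_gt(sum(cells(gt3)$class == "macrophage_intraepithelial"),
            sum(cl$class == "macrophage_intraepithelial"))
})

test_that("an empty configuration yields an empty field", {
  cfg <- simConfig(seed = 1, fieldWidthPx = 300L, fieldHeightPx = 200L,
                   nLobules = 0L)
  gt <- generateField(cfg, "young")
  expect_equal(sum(epitheliumMask(gt)), 0)
  expect_false(any(cells(gt)$class %in% c("luminal", "basal")))
})

test_that("central stromal macrophage density doubles the peripheral one", {
  ## slide-scale fields so a central (>200 um from the fat pad) stromal
  ## region exists; counts pooled over seeds against planted 200:100
  nC <- 0; nP <- 0; aC <- 0; aP <- 0
  for (s in 1:12) {
    cfg <- simConfig(seed = s, fieldWidthPx = 500L, fieldHeightPx = 400L,
                     pixelSizeUm = 3.6416, nLobules = 1L, nTls = 0L)
    gt <- generateField(cfg, "young")
    paren <- parenchymaMask(gt)
    dFat <- EBImage::distmap(paren * 1L) * 3.6416
    central <- stromaMask(gt) & dFat > 200
    cl <- cells(gt)
    mac <- cl[cl$class == "macrophage_stromal", ]
    inC <- central[cbind(round(mac$y_px) + 1L, round(mac$x_px) + 1L)]
    nC <- nC + sum(inC); nP <- nP + sum(!inC)
    aC <- aC + sum(central); aP <- aP + sum(stromaMask(gt) & !central)
  }
  ratio <- (nC / aC) / (nP / aP)
  se <- ratio * sqrt(1 / nC + 1 / nP)    # Poisson error propagation
  expect_gt(nC, 30)
  expect_lt(abs(ratio - 2), 3 * se + 0.2)
})

test_that("Ki67 assignment follows the logistic axis model", {
  set.seed(5)
  n <- 4000
  u <- runif(n)
  cl <- cellRows("luminal", runif(n, 0, 59), runif(n, 0, 49),
                 pi * 9, u = u)
  gt <- makeTruth(cl)

  ## degenerate gradient: frequency matches p0 within binomial 99% CI
  g0 <- assignKi67(gt, p0 = 0.3, slope = 0)
  phat <- mean(cells(g0)$ki67)
  expect_lt(abs(phat - 0.3), 2.576 * sqrt(0.3 * 0.7 / n))

  ## steep slope: sign of u - 0.5 decides
  g1 <- assignKi67(gt, p0 = 0.5, slope = 1e6)
  k <- cells(g1)
  expect_true(all(k$ki67[k$axisU > 0.51]))
  expect_false(any(k$ki67[k$axisU < 0.49]))

  ## quadrature oracle for the mean positivity under a gradient
  g2 <- assignKi67(gt, p0 = 0.2, slope = 4)
  expected <- integrate(function(x) plogis(qlogis(0.2) + 4 * (x - 0.5)),
                        0, 1)$value
  ## u is uniform only approximately in the sample; compare against the
  ## sample-specific expectation
  expSample <- mean(plogis(qlogis(0.2) + 4 * (u - 0.5)))
  expect_lt(abs(mean(cells(g2)$ki67) - expSample),
            2.576 * sqrt(expected * (1 - expected) / n))

  expect_error(assignKi67(gt, p0 = 1.2, slope = 0), "p0")
})

test_that("planted Ki67 gradient is recoverable by regression", {
  gt <- youngField()$gt   # young preset has slope 4
  cl <- cells(gt)
  epi <- cl[cl$class %in% c("luminal", "basal"), ]
  fit <- glm(ki67 ~ axisU, family = binomial, data = epi)
  expect_gt(coef(fit)["axisU"], 0)
  expect_lt(summary(fit)$coefficients["axisU", 4], 0.01)
})

test_that("rendering obeys Beer-Lambert and pairs labels with records", {
  ## no cells, no noise: constant background I0
  gt0 <- makeTruth(cellRows(character(), numeric(), numeric(),
                            numeric()))
  f0 <- renderField(gt0)
  expect_true(all(rgbArray(f0) == 255))

  ## single haematoxylin nucleus: closed-form centre pixel
  gt1 <- makeTruth(cellRows("luminal", 20, 25, pi * 16))
  f1 <- renderField(gt1)
  S <- hdabStainMatrix()
  expect_equal(rgbArray(f1)[26, 21, ], round(255 * exp(-S[, 1])),
               ignore_attr = TRUE)

  ## every planted nucleus owns at least one labelled pixel and label
  ## maps are exclusive
  yf <- youngField()
  lab <- labelMasks(yf$field)
  cl <- cells(yf$gt)
  ids <- sort(unique(c(lab$nuclei[lab$nuclei > 0])))
  expect_identical(ids, cl$cellId)
  expect_false(any(lab$ki67Pos > 0 & lab$ki67Neg > 0))

  ## round trip: OD of a zero-noise render recovers S %*% c at the
  ## quantisation scale
  od <- rgbToOD(rgbArray(f1), 255)
  expect_lt(abs(od[26, 21, 1] - S[1, 1]), 0.02)
})

test_that("emulated measurement tables have the expected structure", {
  tab <- emulateMeasurementTables(seed = 3)
  expect_identical(sort(unique(tab$ageGroup)), c("old", "young"))
  expect_equal(length(unique(tab$animalId)), 13L)
  expect_true(all(c("ki67_epithelial_ratio",
                    "inter_macrophage_distance_um") %in% tab$measure))
  ## deterministic
  expect_identical(tab, emulateMeasurementTables(seed = 3))
  ## forced ordering of the spacing contrast
  sp <- tab[tab$measure == "inter_macrophage_distance_um", ]
  expect_gt(mean(sp$value[sp$ageGroup == "young"]),
            mean(sp$value[sp$ageGroup == "old"]))
  ## degenerate zero-variance config gives identical rows
  p <- measurementDefaults()
  for (m in names(p)) {
    p[[m]]$young["sd"] <- 0; p[[m]]$old["sd"] <- 0
    p[[m]]$young["mean"] <- 1; p[[m]]$old["mean"] <- 1
  }
  tab0 <- emulateMeasurementTables(seed = 1, params = p)
  expect_true(all(tab0$value == 1))
  expect_error(emulateMeasurementTables(nAnimalsPerGroup = 1),
               "at least 2")
})
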