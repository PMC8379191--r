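test_that("optical density transform is the exact inverse pair", {
  ## background pixel: OD approximately zero
  px <- array(255, c(1, 1, 3))
  expect_true(all(rgbToOD(px, 255) == 0))
  ## closed form: I = I0/e - 1 gives OD exactly 1
  px1 <- array(255 / exp(1) - 1, c(1, 1, 3))
  expect_equal(as.numeric(rgbToOD(px1, 255)), rep(1, 3))
  ## exhaustive 8-bit sweep: round trip within one intensity unit
  ## (the clamp of negative OD at saturated pixels costs one level)
  x <- array(rep(0:255, 3), c(256, 1, 3))
  back <- odToRGB(rgbToOD(x, 255), 255)
  expect_lte(max(abs(back - x)), 1)
  expect_true(all(back[1:255, , ] == x[1:255, , ]))
})

test_that("Macenko estimation recovers planted stain vectors", {
  ## zero noise: within 1 degree (raw percentile extremes, no denoise)
  gt <- generateField(simConfig(seed = 11, odNoiseSd = 0), "young")
  f <- renderField(gt)
  sm0 <- estimateStainMatrix(f, smoothSigma = 0)
  ang0 <- stainAngle(stainMatrix(sm0), hdabStainMatrix())
  expect_lt(max(ang0), 1)

  ## noise sigma = 0.05: within 2 degrees with the default estimator
  gt5 <- generateField(simConfig(seed = 11, odNoiseSd = 0.05), "young")
  sm5 <- estimateStainMatrix(renderField(gt5))
  expect_lt(max(stainAngle(stainMatrix(sm5), hdabStainMatrix())), 2)

  ## column identity: haematoxylin first (largest red OD component)
  S <- stainMatrix(sm0)
  expect_gt(S[1, 1], S[1, 2])
})

test_that("degenerate stain inputs behave as specified", {
  ## pure single-stain image: both percentile vectors parallel to it
  S <- hdabStainMatrix()
  set.seed(2)
  conc <- runif(5000, 0.2, 1.5)
  od <- array(0, c(100, 50, 3))
  for (ch in 1:3) od[, , ch] <- conc * S[ch, 1]
  sm <- estimateStainMatrix(odToRGB(od, 255, round8 = FALSE),
                            smoothSigma = 0)
  expect_lt(stainAngle(stainMatrix(sm)[, 1], S[, 1]), 1)
  expect_lt(stainAngle(stainMatrix(sm)[, 2], S[, 1]), 1)

  ## all-white image: estimation error naming the beta filter
  white <- array(255, c(50, 50, 3))
  expect_error(estimateStainMatrix(white), "beta")
})

test_that("normalisation to a reference is faithful and idempotent", {
  gt <- generateField(simConfig(seed = 12, odNoiseSd = 0,
                                fieldWidthPx = 700L,
                                fieldHeightPx = 500L, nLobules = 1L),
                      "young")
  f <- renderField(gt)
  sm <- estimateStainMatrix(f, smoothSigma = 0)

  ## source = reference: identity within one intensity unit
  out <- normalizeToReference(rgbArray(f), sm, sm)
  expect_lte(max(abs(out - rgbArray(f))), 1)

  ## background pixels stay near I0
  bg <- rgbArray(f)[, , 1] >= 254 & rgbArray(f)[, , 2] >= 254 &
    rgbArray(f)[, , 3] >= 254
  expect_lt(max(abs(out[, , 1][bg] - rgbArray(f)[, , 1][bg])), 2)

  ## two renders under different stain matrices, both normalised to a
  ## common reference, nearly coincide
  S2 <- cbind(c(0.55, 0.75, 0.37), c(0.35, 0.55, 0.76))
  S2 <- sweep(S2, 2, sqrt(colSums(S2^2)), "/")
  cfg2 <- simConfig(seed = 12, odNoiseSd = 0, fieldWidthPx = 700L,
                    fieldHeightPx = 500L, nLobules = 1L,
                    stainMatrix = S2)
  f2 <- renderField(gt, config = cfg2)
  sm2 <- estimateStainMatrix(f2, smoothSigma = 0)
  n1 <- normalizeToReference(rgbArray(f), sm, sm)
  n2 <- normalizeToReference(rgbArray(f2), sm2, sm)
  expect_lt(mean(abs(n1 - n2)), 2)

  ## singular source matrix errors
  bad <- stainModel(cbind(c(.65, .7, .29), c(.65, .7, .29)))
  expect_error(normalizeToReference(rgbArray(f), bad, sm), "singular")
})

test_that("stain models serialise losslessly to YAML", {
  sm <- stainModel(hdabStainMatrix(), c(0.8, 1.1), 250)
  p <- tempfile(fileext = ".yaml")
  writeStainModel(sm, p)
  back <- readStainModel(p)
  expect_equal(stainMatrix(back), stainMatrix(sm), ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(maxConcentrations(back), c(0.8, 1.1))
  expect_equal(backgroundIntensity(back), rep(250, 3))
})

test_that("non-negative least squares agrees with clipped pinv in-gamut", {
  S <- hdabStainMatrix()
  cc <- cbind(runif(50, 0, 1.5), runif(50, 0, 1.5))
  od <- array(t(S %*% t(cc)), c(50, 1, 3))
  m <- stainModel(S)
  c1 <- fitConcentrations(od, m, "pinv")
  c2 <- fitConcentrations(od, m, "nnls")
  expect_equal(c1, c2, tolerance = 1e-8)
  ## off-gamut pixel: nnls stays non-negative with lower residual
  odNeg <- array(c(0.9, 0.1, 0.05), c(1, 1, 3))
  c3 <- fitConcentrations(odNeg, m, "nnls")
  expect_true(all(c3 >= 0))
})
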