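test_that("well-separated zero-noise nuclei are counted exactly", {
  ## sparse lattice of nuclei, separation >> diameter
  xs <- rep(seq(20, 180, by = 40), 4)
  ys <- rep(seq(20, 140, by = 40), each = 5)
  ki <- rep(c(TRUE, FALSE), length.out = length(xs))
  cl <- cellRows("luminal", xs, ys, pi * 16, ki67 = ki)
  gt <- makeTruth(cl, w = 200L, h = 160L)
  f <- renderField(gt)
  ms <- segmentNuclei(f, stainModel(hdabStainMatrix()))
  expect_identical(max(ki67PosLabels(ms)), as.integer(sum(ki)))
  expect_identical(max(ki67NegLabels(ms)) - max(ki67PosLabels(ms)),
                   as.integer(sum(!ki)))
  ## phenotype agreement: every planted nucleus centre carries the
  ## right label map
  idx <- cbind(round(cl$y_px) + 1L, round(cl$x_px) + 1L)
  expect_true(all((ki67PosLabels(ms)[idx] > 0) == ki))
})

test_that("a blank field yields empty label maps", {
  white <- array(255, c(80, 100, 3))
  ms <- segmentNuclei(white, stainModel(hdabStainMatrix()),
                      pixelSizeUm = 1)
  expect_equal(max(ki67PosLabels(ms)), 0)
  expect_equal(max(ki67NegLabels(ms)), 0)
  ms <- segmentEpithelium(ms)
  expect_equal(sum(epitheliumMask(ms)), 0)
})

test_that("watershed splits a touching nucleus pair", {
  ## two nuclei overlapping by < 30% of their area
  r <- 6
  cl <- cellRows("luminal", c(40, 40 + 1.55 * r), c(30, 30),
                 rep(pi * r^2, 2))
  gt <- makeTruth(cl, w = 100L, h = 60L)
  f <- renderField(gt)
  ms <- segmentNuclei(f, stainModel(hdabStainMatrix()))
  expect_identical(max(ki67NegLabels(ms)), 2L)
})

test_that("segmentation is deterministic and labels stay exclusive", {
  yf <- youngField()
  m1 <- segmentNuclei(yf$field, yf$stain)
  m2 <- segmentNuclei(yf$field, yf$stain)
  expect_identical(ki67PosLabels(m1), ki67PosLabels(m2))
  expect_false(any(ki67PosLabels(m1) > 0 & ki67NegLabels(m1) > 0))
})

test_that("nucleus count, phenotypes and epithelium recover planted truth", {
  yf <- youngField()
  ms <- segmentEpithelium(segmentNuclei(yf$field, yf$stain))
  cl <- cells(yf$gt)
  nTot <- max(ki67NegLabels(ms))
  expect_lt(abs(nTot / nrow(cl) - 1), 0.05)
  ## phenotype accuracy over planted epithelial nuclei
  epi <- cl[cl$class %in% c("luminal", "basal"), ]
  idx <- cbind(round(epi$y_px) + 1L, round(epi$x_px) + 1L)
  predPos <- ki67PosLabels(ms)[idx] > 0
  expect_gt(mean(predPos == epi$ki67), 0.95)
  expect_gt(diceOf(epitheliumMask(ms), epitheliumMask(yf$gt)), 0.85)
})

test_that("centroid extraction follows the record contract", {
  ## single 3x3 square label at rows/cols 0..2
  pos <- matrix(0L, 10, 12); neg <- matrix(0L, 10, 12)
  pos[1:3, 1:3] <- 1L
  neg[6:8, 9:11] <- 2L
  epi <- matrix(FALSE, 10, 12); epi[1:5, 1:5] <- TRUE
  ms <- new("MaskSet", epithelium = epi, ki67Pos = pos, ki67Neg = neg,
            fieldId = "fx", pixelSizeUm = 1)
  rec <- extractCentroids(ms)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$x_px[1], 1); expect_equal(rec$y_px[1], 1)
  expect_equal(rec$area_px[1], 9)
  expect_true(rec$epithelial[1])   # centroid pixel inside the mask
  expect_false(rec$epithelial[2])
  expect_true(rec$boundary[1])     # touches the field edge
  expect_false(rec$boundary[2])
  expect_identical(rec$nucleusId, sort(rec$nucleusId))

  ## record count equals label count on a real mask set
  yf <- youngField()
  m <- segmentNuclei(yf$field, yf$stain)
  rec2 <- extractCentroids(m)
  nLabels <- length(unique(c(ki67PosLabels(m)[ki67PosLabels(m) > 0],
                             ki67NegLabels(m)[ki67NegLabels(m) > 0])))
  expect_equal(nrow(rec2), nLabels)
})
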