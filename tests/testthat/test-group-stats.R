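test_that("D'Agostino omnibus matches reference values", {
  ## reference values computed once with an independent implementation
  ## of the same published transforms
  x <- c(2.3, 1.9, 3.1, 2.8, 2.2, 1.5, 3.9, 2.7, 2.1, 1.8, 2.6, 3.3)
  r <- dagostinoTest(x)
  expect_equal(r$statistic, 0.7559608790, tolerance = 1e-8)
  expect_equal(r$p.value, 0.6852439042, tolerance = 1e-8)
  expect_equal(r$zSkew, 0.8579947665, tolerance = 1e-8)
  expect_equal(r$zKurt, 0.1407332930, tolerance = 1e-7)
  r2 <- dagostinoTest((1:20)^2)
  expect_equal(r2$statistic, 2.5146974324, tolerance = 1e-8)
  expect_equal(r2$p.value, 0.2844070717, tolerance = 1e-8)
  ## minimum-n boundary
  r3 <- dagostinoTest(c(0.5, 0.7, 1.1, 1.3, 1.8, 2.0, 2.4, 3.0))
  expect_equal(r3$statistic, 0.4266413603, tolerance = 1e-7)
  expect_error(dagostinoTest(rnorm(5)), "n >= 8")
})

test_that("D'Agostino test is calibrated and powered", {
  set.seed(11)
  rej <- mean(replicate(600, dagostinoTest(rnorm(100))$p.value < 0.05))
  expect_lt(abs(rej - 0.05), 2.576 * sqrt(0.05 * 0.95 / 600))
  pow <- mean(replicate(150, dagostinoTest(rexp(200))$p.value < 0.01))
  expect_gte(pow, 0.99)
})

test_that("Mann-Whitney exact branch matches full enumeration", {
  a <- c(1, 2); b <- c(3, 4)
  r <- mannWhitney(a, b)
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  ## independent oracle: enumerate all C(4,2) group assignments
  pooled <- c(a, b)
  uOf <- function(ix) {
    ra <- rank(pooled)[ix]
    sum(ra) - length(ix) * (length(ix) + 1) / 2
  }
  us <- combn(4, 2, uOf)
  pEnum <- mean(us <= r$U) + mean(us >= (4 - r$U))
  expect_equal(r$p.value, 1 / 3)
  expect_equal(pEnum, 1 / 3)

  ## identical samples: no evidence of difference
  expect_gte(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p.value, 0.99)
  expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("Mann-Whitney is rank-based and branch-consistent", {
  set.seed(21)
  a <- rnorm(15); b <- rnorm(15, 0.6)
  p1 <- mannWhitney(a, b)$p.value
  ## invariant under strictly monotone transforms
  expect_equal(mannWhitney(exp(a), exp(b))$p.value, p1)
  expect_equal(mannWhitney(a^3, b^3)$p.value, p1)
  ## exact and normal branches agree near the crossover size
  for (k in 1:20) {
    a <- rnorm(20); b <- rnorm(20, 0.4)
    pe <- mannWhitney(a, b, method = "exact")$p.value
    pn <- mannWhitney(a, b, method = "normal")$p.value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("paired t handles degenerate inputs by convention", {
  a <- c(1, 2, 3, 4)
  expect_equal(pairedT(a, a)$p.value, 1)
  expect_equal(pairedT(c(2, 1, 4, 3), c(1, 2, 3, 4))$t, 0)
  expect_equal(pairedT(c(2, 1, 4, 3), c(1, 2, 3, 4))$p.value, 1)
  expect_error(pairedT(a + 1, a), "undefined")
  expect_error(pairedT(a, a[1:3]), "equal length")
  ## agrees with the standard implementation on regular data
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12, 0.4)
  expect_equal(pairedT(x, y)$p.value,
               t.test(x, y, paired = TRUE)$p.value)
})

test_that("paired t power matches the noncentral-t closed form", {
  set.seed(33)
  n <- 13
  sims <- replicate(1500, pairedT(rnorm(n, 1), rnorm(n, 0))$p.value < 0.05)
  ## differences have sd sqrt(2); effect delta = 1/sqrt(2) sd units
  analytic <- power.t.test(n = n, delta = 1, sd = sqrt(2),
                           type = "paired")$power
  se <- sqrt(analytic * (1 - analytic) / 1500)
  expect_lt(abs(mean(sims) - analytic), 3 * se)
})

test_that("group comparison runs the reported analysis flow", {
  tab <- emulateMeasurementTables(seed = 5)
  cmp <- compareGroups(tab, "inter_macrophage_distance_um")
  expect_match(cmp$test, "Mann-Whitney")
  expect_lt(cmp$p.value, 0.001)
  expect_gt(cmp$groups$mean[cmp$groups$group == "young"],
            cmp$groups$mean[cmp$groups$group == "old"])
  ## normality recorded for groups reaching n >= 8
  expect_false(is.null(cmp$normality$young))

  ## paired central vs peripheral per animal
  cen <- tab[tab$measure == "stromal_mac_density_central", ]
  per <- tab[tab$measure == "stromal_mac_density_peripheral", ]
  per$measure <- "stromal_mac_density_central"
  cen$ageGroup <- "central"; per$ageGroup <- "peripheral"
  both <- rbind(cen, per)
  cmpP <- compareGroups(both, "stromal_mac_density_central",
                        paired = TRUE)
  expect_equal(cmpP$test, "paired t")
  expect_lt(cmpP$p.value, 0.05)   # planted central > peripheral

  ## mismatched animal ids under pairing must error
  perBad <- per; perBad$animalId <- paste0("x", perBad$animalId)
  expect_error(compareGroups(rbind(cen, perBad),
                             "stromal_mac_density_central",
                             paired = TRUE), "matching animal ids")
  expect_error(compareGroups(tab[0, ], "nope"), "no rows")
})

test_that("null group comparisons give uniform p-values", {
  ## a measure with identical group distributions
  ps <- vapply(1:120, function(s) {
    tab <- emulateMeasurementTables(seed = 1000 + s)
    compareGroups(tab, "stromal_t_density")$p.value
  }, numeric(1))
  ## exact Mann-Whitney p-values are discrete, hence tied across
  ## seeds; the KS statistic is still the right uniformity summary
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_gt(min(ps), 0)
})
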