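test_that("presets encode the four study designs", {
  s1 <- simPreset("sim1")
  expect_equal(s1@d, -8.67)
  expect_equal(s1@muG, -5)
  expect_equal(s1@sigmaG, 1)
  expect_equal(s1@sigmaS, 0.7)
  expect_equal(s1@deltaLaw, list(kind = "modlaplace", lambda = 0.5, phi = 0.5))
  expect_equal(s1@kappaLaw, list(kind = "normal", mean = 1, sd = 1))
  expect_equal(s1@tauLaw, list(kind = "normal", mean = 0, sd = 2))
  expect_equal(s1@nControl, 12L)

  s2 <- simPreset("sim2")
  expect_equal(s2@kappaLaw, list(kind = "uniform", min = -1, max = 3))
  expect_equal(s2@tauLaw, list(kind = "uniform", min = -2, max = 2))
  expect_equal(s2@deltaLaw$lambda, 0.5)

  s3 <- simPreset("sim3")
  expect_equal(s3@deltaLaw$lambda, 0.7)
  expect_equal(simPreset("sim3", lambdaDelta = 0.66)@deltaLaw$lambda, 0.66)
  expect_equal(s3@kappaLaw$sd, 0.25)
  expect_equal(s3@tauLaw$kind, "normalmix")
  expect_equal(s3@tauLaw$mean, c(-3, 2))

  s4 <- simPreset("sim4", nControl = 18L, nCase = 18L)
  expect_equal(s4@deltaLaw, list(kind = "fixed", value = 0))
  expect_equal(s4@tauLaw, list(kind = "fixed", value = 0))
  expect_equal(s4@nControl, 18L)
  expect_error(simPreset("sim9"))
})

test_that("simulation is seeded, bounded and explains every missing cell", {
  sc <- simPreset("sim1", S = 40L)
  a <- simulateGels(sc, seed = 3)
  b <- simulateGels(sc, seed = 3)
  expect_identical(intensityMatrix(simGelMatrix(a)),
                   intensityMatrix(simGelMatrix(b)))
  expect_false(identical(intensityMatrix(simGelMatrix(a)),
                         intensityMatrix(simGelMatrix(simulateGels(sc, 4)))))
  v <- intensityMatrix(simGelMatrix(a))
  expect_true(all(v >= sc@d & v <= sc@nu, na.rm = TRUE))
  # missing = not expressed or censored, exclusively explained
  miss <- missingMask(simGelMatrix(a))
  expect_equal(miss, !a@expressed | a@censored)
  expect_true(all(a@expressed[a@censored]))
  expect_equal(nrow(simTruth(a)), 40L)
  expect_equal(simTruth(a)$true_de, simTruth(a)$delta_s != 0 |
                 simTruth(a)$tau_s != 0)

  # full expression and no detection limit: no missing cells
  scFull <- simScenario(S = 20L, nControl = 4L, nCase = 4L,
                        kappaLaw = list(kind = "fixed", value = 50),
                        tauLaw = list(kind = "fixed", value = 0),
                        d = -1e6)
  expect_equal(sum(missingMask(simGelMatrix(simulateGels(scFull, 2)))), 0L)
})

test_that("generated local parameters follow the scenario laws", {
  sc <- simPreset("sim1", S = 10000L, nControl = 2L, nCase = 2L)
  sim <- simulateGels(sc, seed = 17)
  tr <- simTruth(sim)
  expect_equal(mean(tr$mu_s), -5, tolerance = 0.05)
  expect_equal(sd(tr$mu_s), 1, tolerance = 0.05)
  expect_equal(mean(tr$delta_s > 0), 0.5, tolerance = 0.03)
  # |delta| is exponential(0.5): mean 2, and QQ agreement against theory
  expect_equal(mean(abs(tr$delta_s)), 2, tolerance = 0.08)
  qs <- quantile(abs(tr$delta_s), c(0.25, 0.5, 0.75, 0.9))
  expect_equal(unname(qs), qexp(c(0.25, 0.5, 0.75, 0.9), 0.5),
               tolerance = 0.1)
  expect_equal(mean(tr$kappa_s), 1, tolerance = 0.05)
  expect_equal(sd(tr$tau_s), 2, tolerance = 0.06)

  # sim3's tau splits half/half between the two mixture components
  tr3 <- simTruth(simulateGels(simPreset("sim3", S = 1000L,
                                         nControl = 2L, nCase = 2L), 9))
  expect_equal(sum(tr3$tau_s < -1), 500, tolerance = 3)
  expect_equal(mean(tr3$tau_s[tr3$tau_s < -1]), -3, tolerance = 0.05)
  expect_equal(mean(tr3$tau_s[tr3$tau_s > -1]), 2, tolerance = 0.05)
})

test_that("censoring matches the normal tail below the detection limit", {
  # fully expressed spots with many gels: the per-spot censored fraction
  # among expressed cells estimates Phi((d - mu)/sigma)
  sc <- simScenario(S = 6L, nControl = 2000L, nCase = 2000L, muG = -5,
                    sigmaG = 0.8, sigmaS = 0.7,
                    deltaLaw = list(kind = "fixed", value = 0),
                    kappaLaw = list(kind = "fixed", value = 50),
                    tauLaw = list(kind = "fixed", value = 0),
                    d = -6)
  sim <- simulateGels(sc, seed = 23)
  frac <- unname(rowMeans(sim@censored))
  expected <- pnorm((-6 - simTruth(sim)$mu_s) / 0.7)
  expect_equal(frac, expected, tolerance = 0.05)
})

test_that("null datasets are exchangeable across groups", {
  sim <- simulateGels(simPreset("sim4", S = 400L), seed = 29)
  v <- intensityMatrix(simGelMatrix(sim))
  ctrl <- gelGroups(simGelMatrix(sim)) == "control"
  ps <- apply(v, 1L, function(row) {
    a <- row[ctrl]; b <- row[!ctrl]
    if (sum(!is.na(a)) < 3 || sum(!is.na(b)) < 3) return(NA_real_)
    t.test(a, b)$p.value
  })
  rate <- mean(ps < 0.05, na.rm = TRUE)
  n <- sum(!is.na(ps))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.01)
})

test_that("datasets round-trip through the on-disk format", {
  sim <- simulateGels(simPreset("sim1", S = 15L, nControl = 4L, nCase = 4L),
                      seed = 41)
  dir <- tempfile()
  paths <- writeDataset(sim, dir)
  expect_true(all(file.exists(paths)))
  gm2 <- readIntensityTable(paths["gelmatrix"], paths["design"])
  expect_equal(intensityMatrix(gm2), intensityMatrix(simGelMatrix(sim)))
  truth <- read.delim(paths["truth"])
  expect_equal(nrow(truth), 15L)
  expect_equal(truth$true_de, simTruth(sim)$true_de)

  # confusion counts against truth match brute-force set operations
  called <- truth$spot_id[c(1, 3, 5)]
  trueSet <- truth$spot_id[truth$true_de]
  tp <- sum(called %in% trueSet)
  fp <- sum(!(called %in% trueSet))
  fn <- sum(!(trueSet %in% called))
  expect_equal(tp + fp, length(called))
  expect_equal(tp + fn, length(trueSet))
})
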