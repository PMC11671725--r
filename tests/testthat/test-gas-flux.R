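test_that("two-pool forward model and closed-form inversion are exact inverses", {
  # pure pool, no background
  pe <- poolEnrichmentFromExcess(0.5, 0.25, 0)
  expect_equal(poolAtomFraction(pe), 0.5)
  expect_equal(poolFraction(pe), 1)
  # dilute labeled pool over natural background
  xs <- twoPoolForward(0.5, 0.01, 0.0036765)
  expect_equal(unname(xs), c(0.0049267, 0.0024999), tolerance = 1e-4)
  pe <- poolEnrichmentFromExcess(xs[[1]], xs[[2]], 0.0036765)
  expect_equal(poolAtomFraction(pe), 0.5, tolerance = 1e-12)
  expect_equal(poolFraction(pe), 0.01, tolerance = 1e-12)
  # study-level enrichment must round-trip exactly
  xs <- twoPoolForward(0.5114, 0.037, R15_AIR_N2)
  expect_equal(poolAtomFraction(poolEnrichmentFromExcess(xs[[1]], xs[[2]])),
               0.5114, tolerance = 1e-12)
  # property: identity over the full physical domain
  set.seed(4)
  for (i in 1:200) {
    aP <- stats::runif(1, 0.004, 0.99)
    d <- stats::runif(1, 1e-4, 1)
    xs <- twoPoolForward(aP, d)
    pe <- poolEnrichmentFromExcess(xs[[1]], xs[[2]])
    expect_equal(poolAtomFraction(pe), aP, tolerance = 1e-10)
    expect_equal(poolFraction(pe), d, tolerance = 1e-10)
  }
})

test_that("closed-form enrichment agrees with a 2-D numerical root-find oracle", {
  set.seed(5)
  for (i in 1:200) {
    aP <- stats::runif(1, 0.02, 0.95)
    d <- stats::runif(1, 0.001, 1)
    b <- R15_AIR_N2
    xs <- twoPoolForward(aP, d, b)
    root <- twoPoolNumericOracle(xs[[1]], xs[[2]], b)
    pe <- poolEnrichmentFromExcess(xs[[1]], xs[[2]], b)
    expect_equal(poolAtomFraction(pe), root[1], tolerance = 1e-6)
    expect_equal(poolFraction(pe), root[2], tolerance = 1e-6)
  }
})

test_that("enrichment inversion rejects undetectable or inconsistent excesses", {
  expect_error(poolEnrichmentFromExcess(0, 0), "below detection")
  expect_error(poolEnrichmentFromExcess(-1e-6, 1e-6), "below detection")
  # d > 1: more heavy excess than a pure pool could provide
  xs <- twoPoolForward(0.3, 1)
  expect_error(poolEnrichmentFromExcess(xs[[1]] * 1.5, xs[[2]] * 1.5),
               "inconsistent")
})

test_that("excess mole fractions subtract background and flag weak signals", {
  bg <- list(r29 = 0.00735, r30 = 1.35e-5, r45 = 0.00735, r46 = 1.35e-5)
  xs <- excessIsotopologueFractions(bg, bg)
  expect_equal(unname(xs$n2), c(0, 0))
  expect_equal(unname(xs$n2o), c(0, 0))
  expect_true(all(xs$belowDetection))
  smp <- list(r29 = 0.0090, r30 = 4e-4, r45 = 0.0090, r46 = 4e-4)
  xs <- excessIsotopologueFractions(smp, bg)
  expect_false(any(xs$belowDetection))
  expect_true(all(xs$n2 > 0))
  expect_error(excessIsotopologueFractions(smp, NULL), "background")
})

test_that("headspace flux conversion is linear ideal-gas arithmetic", {
  setup <- incubationSetup(headspaceVolume = 0.30, soilMass = 0.15,
                           temperature = 20)
  expect_equal(headspaceFlux(5, 5, 10, setup), 0)
  # 20 ppm over 24 h in 0.30 L at 20 C above 0.15 kg soil
  expect_equal(headspaceFlux(0.33, 20.33, 24, setup), 1.94, tolerance = 0.01)
  setup2 <- incubationSetup(headspaceVolume = 0.60, soilMass = 0.15,
                            temperature = 20)
  expect_equal(headspaceFlux(0.33, 20.33, 24, setup2),
               2 * headspaceFlux(0.33, 20.33, 24, setup))
  expect_error(headspaceFlux(0, 1, 0, setup), "positive")
})

test_that("SPC and macroscopic ratio match the study arithmetic and are scale-free", {
  expect_equal(spcRatio(3, 3), 1)
  expect_equal(spcRatio(0, 3), 0)
  expect_equal(spcRatio(2.2428, 2.31), 0.97091, tolerance = 1e-4)
  expect_error(spcRatio(2, 1), "between 0 and the total")
  expect_equal(macroRatio(5, 0), 1)
  expect_equal(macroRatio(0, 5), 0)
  expect_equal(macroRatio(2.2428, 3.26), 0.40757, tolerance = 1e-4)
  expect_error(macroRatio(0, 0), "both fluxes are zero")
  set.seed(6)
  for (i in 1:20) {
    ab <- stats::rexp(2); k <- stats::rexp(1) + 0.1
    expect_equal(spcRatio(ab[1], ab[1] + ab[2]),
                 spcRatio(k * ab[1], k * (ab[1] + ab[2])))
    expect_equal(macroRatio(k * ab[1], k * ab[2]), macroRatio(ab[1], ab[2]))
  }
})

test_that("gas-flux pipeline inverts a noise-free simulation exactly", {
  tr <- groundTruth()
  tr@noise <- zeroNoise()
  setup <- incubationSetup()
  hs <- simulateIncubation(tr, setup, seed = 1)
  fl <- gasfluxPipeline(hs, setup, precisions = zeroPrecisions)
  expect_equal(fl@n2oTotal[["mean"]], 2.31, tolerance = 1e-9)
  expect_equal(fl@n2Denitrified[["mean"]], 3.26, tolerance = 1e-9)
  expect_equal(fl@spc[["mean"]], 0.97, tolerance = 1e-9)
  expect_equal(fl@aPN2O[["mean"]], 0.5114, tolerance = 1e-9)
  expect_equal(fl@aPN2[["mean"]], 0.5114, tolerance = 1e-9)
  # macroscopic ratio equals the flux identity
  expect_equal(fl@rMacro[["mean"]], 0.97 * 2.31 / (0.97 * 2.31 + 3.26),
               tolerance = 1e-9)
  expect_equal(fl@n2oTotal[["sd"]], 0)
  expect_true(fl@spc[["mean"]] >= 0 && fl@spc[["mean"]] <= 1)
})

test_that("pipeline is invariant to replicate order and flags weak samples", {
  tr <- groundTruth()
  tr@noise <- zeroNoise()
  setup <- incubationSetup()
  hs <- simulateIncubation(tr, setup, seed = 2)
  set.seed(7)
  hsShuffled <- hs[sample(nrow(hs)), ]
  f1 <- gasfluxPipeline(hs, setup, precisions = zeroPrecisions)
  f2 <- gasfluxPipeline(hsShuffled, setup, precisions = zeroPrecisions)
  expect_equal(f1@spc, f2@spc)
  expect_equal(f1@n2oTotal, f2@n2oTotal)
  expect_equal(f1@perReplicate, f2@perReplicate)
  # with the instrument thresholds, early N2 excesses (about 1 sigma at 3 h)
  # are excluded and logged
  fDet <- gasfluxPipeline(hs, setup)
  expect_gt(nrow(fDet@dropped), 0)
  expect_true(all(fDet@dropped$time_h < 24))
  # an inactive incubation is rejected with diagnostics
  flat <- hs
  flat$n2o_ppm <- 0.33
  for (cc in c("r29", "r30", "r45", "r46")) flat[[cc]] <- flat[[cc]][1]
  expect_error(gasfluxPipeline(flat, setup), "below detection")
})

test_that("headspace validation catches schema and domain errors", {
  tr <- groundTruth()
  hs <- simulateIncubation(tr, seed = 1)
  expect_silent(checkHeadspace(hs))
  expect_error(checkHeadspace(hs[, -3]), "missing columns")
  bad <- hs; bad$r30[2] <- -1
  expect_error(checkHeadspace(bad), "non-negative")
  one <- hs[hs$replicate == "R1" & hs$time_h == 0, ]
  expect_error(gasfluxPipeline(one), "at least 2 time points")
})
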