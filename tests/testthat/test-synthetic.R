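# Synthetic-data generator: structure, determinism, calibration.

test_that("trait simulation is deterministic and carries the design structure", {
  cfg <- simulationConfig(seed = 7)
  t1 <- simulateTraits(cfg)
  t2 <- simulateTraits(cfg)
  expect_identical(t1, t2)
  # 12 plots x 5 dates
  expect_equal(nrow(t1), 12 * 5)
  expect_true(validateTraitTable(t1))
  # noise-free curves: mixed plots lose extra leaf area on the last date
  cfg0 <- simulationConfig(seed = 7, traitSd = c(leaf_chl = 0, lai = 0))
  t0 <- simulateTraits(cfg0)
  last <- t0[t0$dap == 99, ]
  expect_lt(mean(last$lai[last$treatment == "mixed"]),
            mean(last$lai[last$treatment == "non-mixed"]))
  # leaf chlorophyll declines monotonically in expectation
  chl <- tapply(t0$leaf_chl[t0$treatment == "non-mixed"],
                t0$dap[t0$treatment == "non-mixed"], mean)
  expect_true(all(diff(chl) < 0))
  # lai rises then declines
  lai <- tapply(t0$lai[t0$treatment == "non-mixed"],
                t0$dap[t0$treatment == "non-mixed"], mean)
  expect_gt(lai[["75"]], lai[["43"]])
  expect_lt(lai[["99"]], lai[["84"]])
})

test_that("trait noise matches the configured standard deviations", {
  cfg <- simulationConfig(seed = 13, nBlocks = 250,
                          traitSd = c(leaf_chl = 2, lai = 0.25))
  tr <- simulateTraits(cfg)   # 1000 plots x 5 dates
  oneDate <- tr[tr$dap == 75 & tr$treatment == "non-mixed", ]
  expect_equal(sd(oneDate$leaf_chl), 2, tolerance = 0.1)
  expect_equal(sd(oneDate$lai), 0.25, tolerance = 0.1)
})

test_that("the reflectance forward model matches its closed form and monotonicities", {
  bs <- uavBandSet()
  wl <- bandCenters(bs)
  expect_equal(vegetationReflectance(40, 3, bs), refModelOracle(40, 3, wl),
               tolerance = 1e-12)
  i670 <- resolveBand(bs, 670); i800 <- resolveBand(bs, 800)
  # no chlorophyll -> no red trough
  expect_gte(vegetationReflectance(0, 3, bs)[i670],
             vegetationReflectance(50, 3, bs)[i670])
  # doubling lai raises the NIR plateau
  expect_gt(vegetationReflectance(40, 4, bs)[i800],
            vegetationReflectance(40, 2, bs)[i800])
  expect_error(vegetationReflectance(-1, 3, bs), ">= 0")
})

test_that("two-sensor simulation carries the row-sampling contrast", {
  cfg0 <- simulationConfig(seed = 3, spectralSd = 0, rowConcentration = 1,
                           groundBands = uavBandSet())
  tr <- simulateTraits(cfg0)
  sp <- simulateTwoSensorSpectra(tr, cfg0)
  # row concentration 1, no noise: plot-mean spectra agree at shared bands
  mu <- aggregatePlot(sp$uav[[1]])
  mg <- aggregatePlot(sp$ground[[1]])
  expect_equal(mu, mg, tolerance = 1e-12)
  # fully covered plot: spectra independent of the soil endmember
  cfgA <- simulationConfig(seed = 5, spectralSd = 0)
  cfgB <- simulationConfig(seed = 5, spectralSd = 0,
                           soilSpectrum = function(wl) rep(0.5, length(wl)))
  trFull <- simulateTraits(cfgA)[1, ]
  trFull$ground_cover <- 1
  sA <- simulateTwoSensorSpectra(trFull, cfgA)$ground[[1]]
  sB <- simulateTwoSensorSpectra(trFull, cfgB)$ground[[1]]
  expect_equal(reflectance(sA), reflectance(sB), tolerance = 1e-12)
  # ground NDVI >= UAV NDVI in expectation at partial cover
  cfg <- simulationConfig(seed = 9, rowConcentration = 1.3)
  tr2 <- simulateTraits(cfg)
  sp2 <- simulateTwoSensorSpectra(tr2, cfg)
  viU <- indexTable(sp2$uav, indices = "NDVI")
  viG <- indexTable(sp2$ground, indices = "NDVI")
  m <- merge(viU, viG, by = c("plot_id", "dap"))
  expect_gt(mean(m$NDVI.y - m$NDVI.x), 0)
  expect_gt(mean(m$NDVI.y >= m$NDVI.x), 0.8)
})

test_that("gap-field generator is calibrated to the target clumping", {
  # omega 1: homogeneous cells, logarithmic averaging returns 1
  g1 <- simulateGapField(3, 45, 1, seed = 1)
  expect_true(all(apply(gapFractions(g1[[1]]), 1, function(r) diff(range(r)) == 0)))
  expect_equal(unname(clumpingLangXiang(g1, 45)), rep(1, 15), tolerance = 1e-9)
  # empty canopy
  g0 <- simulateGapField(0, 45, 0.9, seed = 2)
  expect_true(all(gapFractions(g0[[1]]) == 1))
  # calibration: Eq-1 clumping on the generated field within +/-0.02
  g <- simulateGapField(3, 40, 0.8, seed = 3)
  om <- clumpingLangXiang(g, 40)
  expect_true(all(om >= 0.78 & om <= 0.82))
  # ring means obey the clumped Poisson model
  th <- ringCenters()
  stats <- sapply(1:15, function(i) {
    gg <- unlist(lapply(g, function(x) gapFractions(x)[i, ]))
    ww <- unlist(lapply(g, function(x) cellCounts(x)[i, ]))
    sum(gg * ww) / sum(ww)
  })
  expect_equal(stats, gapModel(3, 40, 0.8, th), tolerance = 1e-6)
  expect_error(simulateGapField(3, 40, 0, seed = 1), "omegaTarget")
  # determinism
  expect_identical(lapply(simulateGapField(2, 50, 0.85, seed = 7), gapFractions),
                   lapply(simulateGapField(2, 50, 0.85, seed = 7), gapFractions))
})

test_that("mosaic simulation writes exact rectangles and is seed-stable", {
  lay <- defaultStripLayout(3)
  m0 <- simulateMosaic(lay, viLevels = 0.6, soilLevel = 0.1, noiseSd = 0, seed = 1)
  v <- m0@values[, , 1]
  expect_setequal(unique(as.vector(v)), c(0.1, 0.6))
  # plot 1 occupies exactly its rectangle (pixel-center rule)
  inPlot <- v == 0.6
  expect_equal(sum(inPlot), sum(lay$width / 0.2 * lay$height / 0.2))
  expect_identical(simulateMosaic(lay, seed = 5)@values,
                   simulateMosaic(lay, seed = 5)@values)
  bad <- lay; bad$y0[2] <- bad$y0[1] + 1
  expect_error(simulateMosaic(bad), "overlapping")
})
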