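# Vegetation index library.

mkSpec <- function(bs, assign) {
  r <- rep(0.1, nBands(bs))
  for (nm in names(assign)) r[resolveBand(bs, as.numeric(nm))] <- assign[[nm]]
  r
}

test_that("band resolution matches nearest centers within tolerance", {
  uav <- uavBandSet(); grd <- groundBandSet()
  expect_equal(bandCenters(uav)[resolveBand(uav, 800)], 800)
  expect_equal(bandCenters(grd)[resolveBand(grd, 754)], 750)   # red-edge MTCI band
  expect_equal(bandCenters(uav)[resolveBand(uav, 705)], 700)   # tie toward shorter
  expect_error(resolveBand(uav, 1650), "no band within")
})

test_that("index formulas reproduce hand-computed values", {
  bs <- uavBandSet()
  expect_equal(computeIndex(mkSpec(bs, list(`670` = 0.2, `800` = 0.2)), "NDVI", bs), 0)
  expect_equal(computeIndex(mkSpec(bs, list(`670` = 0.05, `800` = 0.45)), "NDVI", bs), 0.8)
  expect_equal(computeIndex(mkSpec(bs, list(`670` = 0.05, `800` = 0.45)), "OSAVI", bs),
               1.16 * 0.40 / 0.66)
  expect_equal(computeIndex(mkSpec(bs, list(`550` = 0.09, `780` = 0.45)), "CI_g", bs), 4)
  expect_equal(computeIndex(mkSpec(bs, list(`550` = 0.13, `670` = 0.13, `700` = 0.13)),
                            "MCARI", bs), 0)
  # REP interpolation endpoints
  rep1 <- mkSpec(bs, list(`670` = 0.05, `700` = 0.25, `740` = 0.30, `780` = 0.45))
  expect_equal(computeIndex(rep1, "REP", bs), 700)
  rep2 <- mkSpec(bs, list(`670` = 0.05, `700` = 0.10, `740` = 0.25, `780` = 0.45))
  expect_equal(computeIndex(rep2, "REP", bs), 740)
})

test_that("soil line estimation and WDVI behave as defined", {
  grd <- groundBandSet()
  soil <- mkSpec(grd, list(`670` = 0.10, `870` = 0.12))
  expect_equal(estimateSoilLine(soil, grd), 1.2)
  soil2 <- rbind(soil, soil * 2)   # identical ratios
  expect_equal(estimateSoilLine(soil2, grd), 1.2)
  # WDVI of pure soil under its own soil line is 0
  expect_equal(computeIndex(soil, "WDVI", grd, soilLine = 1.2), 0)
  expect_error(computeIndex(soil, "WDVI", grd), "soil line")
  expect_error(estimateSoilLine(matrix(numeric(0), 0, 11), grd), "no soil")
})

test_that("index scale behavior matches each formulation", {
  set.seed(21)
  bs <- uavBandSet()
  r <- runif(nBands(bs), 0.02, 0.6)
  # pure band-ratio formulations are invariant to a positive rescaling
  for (nm in c("NDVI", "CI_re", "CI_g", "MTCI", "PRI", "REP")) {
    expect_equal(computeIndex(r, nm, bs), computeIndex(3.7 * r, nm, bs),
                 tolerance = 1e-10, label = nm)
  }
  # difference-based formulations are homogeneous of degree 1
  for (nm in c("WDVI", "MCARI", "TCARI")) {
    expect_equal(computeIndex(2 * r, nm, bs, soilLine = 1.2),
                 2 * computeIndex(r, nm, bs, soilLine = 1.2),
                 tolerance = 1e-10, label = nm)
  }
  # soil-adjusted forms (additive 0.16 / MCARI2 discriminant) are neither:
  # rescaling changes OSAVI
  expect_false(isTRUE(all.equal(computeIndex(r, "OSAVI", bs),
                                computeIndex(2 * r, "OSAVI", bs))))
})

test_that("NDVI and OSAVI stay within their theoretical bounds", {
  set.seed(22)
  bs <- groundBandSet()
  for (i in 1:50) {
    r <- runif(nBands(bs), 0, 1)
    expect_true(abs(computeIndex(r, "NDVI", bs)) <= 1)
    expect_true(abs(computeIndex(r, "OSAVI", bs)) <= 1.16)
  }
})

test_that("each sensor uses its own nominal band centers", {
  # ground NDVI uses 780 nm, not 870; make them differ
  grd <- groundBandSet()
  r <- mkSpec(grd, list(`670` = 0.1, `780` = 0.5, `870` = 0.9))
  expect_equal(computeIndex(r, "NDVI", grd), (0.5 - 0.1) / (0.5 + 0.1))
  # ground MTCI uses 670/710/750
  r2 <- mkSpec(grd, list(`670` = 0.05, `710` = 0.20, `750` = 0.50))
  expect_equal(computeIndex(r2, "MTCI", grd), (0.50 - 0.20) / (0.20 - 0.05))
})

test_that("index maps equal the pixelwise oracle and mask undefined pixels", {
  set.seed(23)
  bs <- uavBandSet()
  vals <- array(runif(8 * 8 * nBands(bs), 0.02, 0.6), c(8, 8, nBands(bs)))
  cube <- HyperCube(bs, vals)
  map <- indexMap(cube, "NDVI")
  oracle <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- computeIndex(vals[i, j, ], "NDVI", bs)
  expect_equal(map@values[, , 1], oracle)
  # constant cube -> constant map
  cc <- HyperCube(bs, array(0.3, c(4, 4, nBands(bs))))
  expect_true(all(indexMap(cc, "OSAVI")@values == indexMap(cc, "OSAVI")@values[1, 1, 1]))
  # zero-denominator pixel is masked, others computed
  vals2 <- vals
  vals2[3, 3, ] <- 0
  m2 <- indexMap(HyperCube(bs, vals2), "NDVI")@values[, , 1]
  expect_true(is.na(m2[3, 3]))
  expect_false(anyNA(m2[-3, ]))
})
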