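# Hemispherical-photograph canopy inversion.

test_that("ellipsoidal G-function has the expected limits", {
  expect_equal(gFunction(0, 1), 0.4997, tolerance = 1e-4)
  # spherical distribution: G constant over zenith
  expect_lt(abs(gFunction(60, 1) - gFunction(0, 1)), 0.001)
  expect_true(all(abs(gFunction(seq(0, 80, 5), 1) - 0.5) < 0.001))
  # planophile extreme: G -> 1 at nadir
  expect_gt(gFunction(0, 100), 0.99)
  expect_error(gFunction(10, -1), "positive")
})

test_that("chi and average leaf angle conversions are consistent inverses", {
  for (ala in seq(15, 75, 10))
    expect_equal(alaFromChi(chiFromAla(ala)), ala, tolerance = 1e-9)
  expect_equal(alaFromChi(1), 56.12, tolerance = 0.01)
})

test_that("the Poisson gap model behaves as defined", {
  expect_equal(gapModel(0, 45, 1, 20), 1)
  expect_equal(gapModel(2, alaFromChi(1), 1, 0), exp(-2 * gFunction(0, 1)))
  # omega scales the exponent
  p1 <- gapModel(3, 40, 1, 25); p05 <- gapModel(3, 40, 0.5, 25)
  expect_equal(log(p05), 0.5 * log(p1))
  expect_error(gapModel(1, 40, 1, 95), "90")
  # monotone decreasing in lai and omega
  lais <- seq(0, 8, 0.5)
  expect_true(all(diff(gapModel(lais, 50, 0.9, 15)) < 0))
  oms <- seq(0.1, 1, 0.1)
  expect_true(all(diff(gapModel(3, 50, oms, 15)) < 0))
})

test_that("logarithmic gap averaging reproduces hand-computed clumping", {
  # all cells equal -> 1
  g <- GapFractionGrid(matrix(0.4, 15, 72))
  expect_equal(unname(clumpingLangXiang(g, 57)), rep(1, 15))
  # two equal-weight cells with gaps e^-1 and e^-3 (hand: ln(mean)/(-2))
  gap <- matrix(NA_real_, 15, 72); cnt <- matrix(0, 15, 72)
  gap[1, 1] <- exp(-1); gap[1, 2] <- exp(-3); cnt[1, 1:2] <- 1
  hand <- log((exp(-1) + exp(-3)) / 2) / -2
  expect_equal(clumpingLangXiang(GapFractionGrid(gap, cnt), 57, rings = 1), hand,
               tolerance = 1e-9)
  # Jensen: any heterogeneous ring gives omega < 1
  set.seed(31)
  for (i in 1:10) {
    gh <- matrix(runif(15 * 72, 0.05, 0.95), 15, 72)
    om <- clumpingLangXiang(GapFractionGrid(gh), 57)
    expect_true(all(om < 1 & om > 0))
  }
  expect_error(clumpingLangXiang(GapFractionGrid(gap, cnt), 57, rings = 5),
               "no populated")
})

test_that("ground cover uses the 0-20 degree rings, count-weighted", {
  expect_equal(groundCover(GapFractionGrid(matrix(0, 15, 72))), 1)
  expect_equal(groundCover(GapFractionGrid(matrix(0.25, 15, 72))), 0.75)
  # mixed rings: brute-force weighted mean over rings 1-8
  set.seed(32)
  gap <- matrix(runif(15 * 72), 15, 72)
  cnt <- matrix(sample(0:5, 15 * 72, TRUE), 15, 72)
  gap[cnt == 0] <- NA
  g <- GapFractionGrid(gap, cnt)
  sel <- cnt[1:8, ] > 0
  oracle <- 1 - sum(gap[1:8, ][sel] * cnt[1:8, ][sel]) / sum(cnt[1:8, ][sel])
  expect_equal(groundCover(g), oracle)
})

test_that("vegetation segmentation separates green canopy from soil", {
  # uniform images
  green <- array(rep(c(0.1, 0.5, 0.1), each = 100), c(10, 10, 3))
  expect_true(all(classifyVegetation(green) == 1))
  soil <- array(rep(c(0.5, 0.45, 0.4), each = 100), c(10, 10, 3))
  expect_true(all(classifyVegetation(soil) == 0))
  # bimodal scene with mild channel noise: misclassification < 2%
  set.seed(33)
  truth <- matrix(runif(150 * 150) < 0.4, 150)
  img <- array(0, c(150, 150, 3))
  base <- list(soil = c(0.5, 0.45, 0.4), veg = c(0.10, 0.45, 0.10))
  for (ch in 1:3) {
    m <- matrix(base$soil[ch], 150, 150)
    m[truth] <- base$veg[ch]
    img[, , ch] <- m + matrix(rnorm(150 * 150, 0, 0.02), 150)
  }
  mask <- classifyVegetation(img)
  expect_lt(mean(mask != truth), 0.02)
  expect_error(classifyVegetation(matrix(1, 5, 5)), "RGB")
})

test_that("angular binning conserves pixels and respects the projection", {
  set.seed(34)
  mask <- matrix(as.integer(runif(200 * 200) > 0.3), 200)  # 30% gaps
  g <- binToGrid(mask)
  # only pixels within 37.5 degrees of the axis are binned
  expect_true(sum(cellCounts(g)) < length(mask))
  expect_gt(sum(cellCounts(g)), 0)
  pop <- cellCounts(g) > 20
  expect_true(all(abs(gapFractions(g)[pop] - 0.3) < 0.25))
  # exact conservation: the count-weighted mean gap equals the gap-pixel
  # fraction of the binned region
  rowsM <- matrix(seq_len(200), 200, 200)
  zenM <- sqrt((rowsM - 100.5)^2 + (t(rowsM) - 100.5)^2) / 100 * 90
  expect_equal(weighted.mean(gapFractions(g), cellCounts(g), na.rm = TRUE),
               mean(mask[zenM < 37.5] == 0), tolerance = 1e-12)
  # constructed truth: vegetation only inside 20 degrees zenith
  nr <- 201
  rows <- matrix(seq_len(nr), nr, nr)
  cols <- t(rows)
  zen <- sqrt((rows - 101)^2 + (cols - 101)^2) / 100.5 * 90
  mask2 <- matrix(0L, nr, nr)
  mask2[zen <= 20] <- 1L
  g2 <- binToGrid(mask2)
  om <- gapFractions(g2)
  pop2 <- cellCounts(g2) > 0
  # rings fully below 20 deg vegetated, rings above fully gap
  expect_true(all(om[1:7, ][pop2[1:7, ]] == 0))
  expect_true(all(om[10:15, ][pop2[10:15, ]] == 1))
  # pixel count conservation against direct count within the 37.5 deg circle
  expect_equal(sum(cellCounts(g2)), sum(zen < 37.5))
})

test_that("LUT inversion recovers noise-free forward fields", {
  g <- simulateGapField(3, 40, 1, seed = 41)
  cp <- invertCanopy(g)
  expect_true(canopyLai(cp) >= 2.95 && canopyLai(cp) <= 3.05)
  expect_true(canopyAla(cp) %in% c(38, 40, 42))
  # empty canopy
  g0 <- simulateGapField(0, 40, 1, seed = 42)
  expect_equal(canopyLai(invertCanopy(g0)), 0)
  # 1% gap noise moves the retrieved PAI by less than 0.2
  gn <- simulateGapField(3, 40, 0.85, seed = 43, noiseSd = 0.01)
  gc <- simulateGapField(3, 40, 0.85, seed = 43)
  expect_lt(abs(canopyLai(invertCanopy(gn)) - canopyLai(invertCanopy(gc))), 0.2)
})

test_that("vectorized inversion equals an independently coded brute-force search", {
  lutSmall <- new("LutSpec", laiGrid = seq(0, 6, 0.1),
                  alaGrid = seq(20, 70, 10), effAlaGrid = seq(20, 70, 10))
  set.seed(44)
  cases <- list(c(2.0, 30, 0.8), c(0.5, 50, 1.0), c(4.0, 60, 0.75),
                c(1.2, 40, 0.9), c(3.3, 20, 0.95))
  for (cs in cases) {
    g <- simulateGapField(cs[1], cs[2], cs[3], seed = round(100 * cs[1]),
                          noiseSd = 0.02)
    fast <- invertCanopy(g, lut = lutSmall)
    slow <- bruteInvert(g, lutSmall)
    expect_equal(canopyLai(fast), slow$lai)
    expect_equal(canopyAla(fast), slow$ala)
    expect_equal(fast@omegaEffAla, slow$eff)
    expect_equal(fast@cost, slow$cost, tolerance = 1e-10)
  }
})
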