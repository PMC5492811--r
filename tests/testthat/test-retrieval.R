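# VI-to-trait retrieval statistics.

test_that("SPAD conversion and canopy chlorophyll arithmetic", {
  expect_equal(spadToChl(0, list(a = 5, b = 0.04)), 5)
  expect_gt(spadToChl(40, list(a = 5, b = 0.04)), spadToChl(30, list(a = 5, b = 0.04)))
  expect_error(spadToChl(30, list(a = 5, b = 0)), "increasing")   # degenerate calib
  expect_error(spadToChl(-1, list(a = 5, b = 0.04)), ">= 0")
  expect_equal(canopyChlorophyll(40, 3), 1.2)
  expect_equal(canopyChlorophyll(40, 0), 0)
  # bilinear
  expect_equal(canopyChlorophyll(20, 3) + canopyChlorophyll(20, 3),
               canopyChlorophyll(40, 3))
  expect_equal(canopyChlorophyll(40, 1.5) * 2, canopyChlorophyll(40, 3))
})

test_that("OLS fit matches exact lines and the normal-equation oracle", {
  x <- 1:20
  f <- fitOls(x, 2 * x + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1); expect_equal(f$r2, 1)
  # constant response
  fc <- fitOls(x, rep(3, 20))
  expect_equal(fc$slope, 0); expect_equal(fc$r2, 0)
  set.seed(51)
  xn <- runif(40); yn <- 1.5 * xn + rnorm(40, 0, 0.3)
  fn <- fitOls(xn, yn)
  oracle <- olsOracle(xn, yn)
  expect_equal(fn$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fn$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
  # r2 equals squared Pearson correlation for simple regression
  expect_equal(fn$r2, cor(xn, yn)^2, tolerance = 1e-12)
  expect_error(fitOls(1:2, 1:2), "at least 3")
  expect_error(fitOls(rep(1, 5), 1:5), "variance")
})

test_that("repeated k-fold cross-validation recovers the noise level", {
  x <- seq(0, 1, length.out = 50)
  expect_lt(cvRmse(x, 3 * x - 1, seed = 1), 1e-10)
  set.seed(52)
  xn <- runif(600); yn <- xn + rnorm(600, 0, 0.5)
  cv <- cvRmse(xn, yn, k = 10, repeats = 100, seed = 2)
  expect_true(cv > 0.45 && cv < 0.55)
  expect_identical(cvRmse(xn, yn, seed = 5), cvRmse(xn, yn, seed = 5))
  expect_error(cvRmse(1:5, 1:5, k = 10), "at least k")
})

test_that("cross-validated RMSE exceeds the full-fit RMSE in expectation", {
  set.seed(53)
  diffs <- replicate(50, {
    x <- runif(40); y <- x + rnorm(40, 0, 0.4)
    fullRmse <- sqrt(mean((y - predictTrait(
      fitRetrieval(x, y, repeats = 5, seed = 1), x))^2))
    cvRmse(x, y, repeats = 5, seed = 1) - fullRmse
  })
  expect_gt(t.test(diffs, alternative = "greater")$p.value < 0.05, 0)
  expect_gt(mean(diffs), 0)
})

test_that("confidence and prediction bands follow the OLS formulas", {
  set.seed(54)
  x <- runif(30); y <- 2 * x + rnorm(30, 0, 0.2)
  m <- fitRetrieval(x, y, repeats = 5, seed = 1)
  grid <- seq(min(x), max(x), length.out = 21)
  b <- intervals(m, grid)
  expect_true(all(b$pred_lo < b$conf_lo & b$pred_hi > b$conf_hi))
  # narrowest at mean(x)
  widths <- b$conf_hi - b$conf_lo
  atMean <- intervals(m, mean(x))
  expect_true(all(atMean$conf_hi - atMean$conf_lo <= widths + 1e-12))
  # closed-form width at mean(x): 2 * t * s * sqrt(1/n)
  res <- y - predictTrait(m, x)
  s <- sqrt(sum(res^2) / (30 - 2))
  tq <- qt(0.975, 28)
  expect_equal(atMean$conf_hi - atMean$conf_lo, 2 * tq * s * sqrt(1 / 30),
               tolerance = 1e-12)
  expect_error(intervals(m, grid, level = 1.2), "level")
})

test_that("per-date mean errors match the groupwise oracle and sum to zero", {
  set.seed(55)
  x <- runif(60); dap <- rep(c(43, 62, 75, 84, 99), each = 12)
  y <- 1.2 * x + rnorm(60, 0, 0.3)
  m <- fitRetrieval(x, y, dap = dap, repeats = 5, seed = 1)
  me <- meanErrorByDate(m, x, y, dap)
  res <- y - predictTrait(m, x)
  oracle <- tapply(res, dap, mean)
  expect_equal(unname(me), unname(as.numeric(oracle)))
  # OLS residuals: group-size-weighted mean errors sum to ~0
  expect_lt(abs(sum(me * table(dap))), 1e-9)
  # perfect model, constant shift
  mPerf <- fitRetrieval(x, 2 * x, repeats = 5, seed = 1)
  expect_true(all(abs(meanErrorByDate(mPerf, x, 2 * x, dap)) < 1e-12))
  expect_true(all(abs(meanErrorByDate(mPerf, x, 2 * x + 1, dap) - 1) < 1e-12))
})

test_that("the model matrix covers all combinations and flags the best", {
  set.seed(56)
  n <- 40
  traits <- data.frame(plot_id = sprintf("p%d", 1:n), dap = rep(c(1, 2), n / 2),
                       ground_cover = runif(n), lai = runif(n, 0, 5))
  # NDVI constructed to track ground cover; MTCI pure noise
  vi <- data.frame(plot_id = traits$plot_id, dap = traits$dap, sensor = "uav",
                   NDVI = traits$ground_cover + rnorm(n, 0, 0.02),
                   MTCI = rnorm(n))
  mm <- modelMatrix(vi, traits, indices = c("NDVI", "MTCI"),
                    traitNames = c("ground_cover", "lai"), repeats = 10, seed = 1)
  expect_equal(nrow(mm), 4)
  expect_equal(sum(mm$best), 2)
  for (tr in unique(mm$trait)) {
    sub <- mm[mm$trait == tr, ]
    expect_true(sub$best[which.min(sub$rmse_cv)])
  }
  expect_equal(mm$index[mm$trait == "ground_cover" & mm$best], "NDVI")
})
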