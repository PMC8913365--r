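test_that("generators are bit-reproducible given (config, seed)", {
  g <- gridDef(6, 6)
  a <- simulateClimate(g, 2015:2017, seed = 50)
  b <- simulateClimate(g, 2015:2017, seed = 50)
  expect_identical(gridValues(a$dfmc), gridValues(b$dfmc))
  expect_identical(gridValues(a$vpd), gridValues(b$vpd))
  truth1 <- syntheticTruth(g, seed = 50)
  truth2 <- syntheticTruth(g, seed = 50)
  expect_identical(truth1@kernels, truth2@kernels)
  l1 <- simulateLfmc(a$dfmc, truth1, seed = 50)
  l2 <- simulateLfmc(b$dfmc, truth2, seed = 50)
  expect_identical(gridValues(l1), gridValues(l2))
  tr1 <- simulateTraits(truth1, coarseFactor = 2, seed = 50)
  tr2 <- simulateTraits(truth2, coarseFactor = 2, seed = 50)
  expect_identical(tr1@layers, tr2@layers)
  # a different seed changes the draw
  expect_false(identical(gridValues(a$dfmc),
                         gridValues(simulateClimate(g, 2015:2017, seed = 51)$dfmc)))
})

test_that("zero anomaly variance collapses the climate to its seasonal cycle", {
  g <- gridDef(3, 3)
  clim <- simulateClimate(g, 2016:2017, seed = 52, dfmcAnomSd = 0,
                          vpdAnomSd = 0, vpdYearSd = 0)
  cal <- calendarOf(clim$dfmc)
  y1 <- which(cal$year == 2016); y2 <- which(cal$year == 2017)
  expect_equal(gridValues(clim$dfmc)[, y1], gridValues(clim$dfmc)[, y2])
  an <- anomaly(clim$dfmc, seasonalClimatology(clim$dfmc, minYears = 1))
  expect_lt(max(abs(gridValues(an))), 1e-9)
  expect_error(simulateClimate(g, 2016:2017, seed = 1, dfmcAnomSd = -1),
               "non-negative")
})

test_that("anomalies carry the configured AR(1) autocorrelation", {
  g <- gridDef(1, 1)
  clim <- simulateClimate(g, 1938:2020, seed = 53)   # ~2000 epochs
  an <- anomaly(clim$dfmc, seasonalClimatology(clim$dfmc, minYears = 1))
  x <- as.numeric(gridValues(an))
  rho <- cor(x[-1], x[-length(x)])
  expect_equal(rho, 0.7, tolerance = 0.05)
})

test_that("a configured VPD trend is recovered by the trend map", {
  g <- gridDef(8, 8)
  clim <- simulateClimate(g, 1980:2020, seed = 54, vpdTrend = 0.05)
  annual <- fireYearAggregate(clim$vpd, 1, "mean")
  tm <- vpdTrendMap(annual)
  # the shared interannual VPD component correlates errors across pixels,
  # so judge recovery against the OLS standard error of the domain mean
  domain <- olsSlope(colMeans(gridValues(annual)), annual@years)
  expect_lt(abs(domain$slope - 0.05), 2 * domain$stderr)
  expect_equal(mean(trendValues(tm)), domain$slope, tolerance = 1e-9)
  expect_gt(mean(trendValues(tm) > 0), 0.9)
})

test_that("the LFMC generator validates kernels and honours missingness", {
  g <- gridDef(4, 4)
  truth <- syntheticTruth(g, seed = 55)
  clim <- simulateClimate(g, 2015:2016, seed = 55)
  bad <- truth
  bad@kernels <- truth@kernels[, 1:7]
  expect_error(simulateLfmc(clim$dfmc, bad, seed = 55), "kernel length")
  lf <- simulateLfmc(clim$dfmc, truth, missingFrac = 0.3, seed = 55)
  frac <- mean(is.na(gridValues(lf)[, -(1:10)]))
  expect_equal(frac, 0.3, tolerance = 0.05)
})

test_that("the fire generator enforces the affine slope law", {
  g <- gridDef(12, 12)
  clim <- simulateClimate(g, 2015:2020, seed = 56)
  vpdAnnual <- fireYearAggregate(clim$vpd, 4, "mean")
  # flat law (b = 0), no noise: every bin slope is a
  flat <- syntheticTruth(g, seed = 56, a = 350, b = 0)
  baFlat <- simulateFire(flat, vpdAnnual, baNoiseSd = 0, seed = 56)
  pm <- new("PWSMap", grid = g, pws = truePws(flat), r2 = rep(1, 144),
            nObs = rep(60L, 144), zeroFraction = rep(0, 144),
            valid = rep(TRUE, 144))
  bins <- equalAreaBins(pm, k = 6)
  bs <- binSlopes(binAnnualSeries(baFlat, vpdAnnual, bins))
  # bins hold 144/6 = 24 pixels against the 144/15 reference: slopes scale
  expect_equal(bs$slope, rep(350 * (144 / 6) / (144 / 15), 6), tolerance = 0.02)
  # clipping never yields negative burned area
  noisy <- simulateFire(syntheticTruth(g, seed = 57), vpdAnnual,
                        baNoiseSd = 50, seed = 57)
  expect_true(all(gridValues(noisy) >= 0))
  # a law that goes negative warns
  neg <- syntheticTruth(g, seed = 58, a = -5000, b = 0)
  expect_warning(simulateFire(neg, vpdAnnual, baNoiseSd = 0, seed = 58),
                 "negative")
})

test_that("trait stacks respect bounds, coding and coarse structure", {
  g <- gridDef(16, 16)
  truth <- syntheticTruth(g, seed = 59)
  traits <- simulateTraits(truth, coarseFactor = 8, noiseSd = 0.3, seed = 59)
  expect_equal(length(traits@layers), 14)
  for (nm in c("sand", "silt", "clay")) {
    v <- asPixelVector(getLayer(traits, nm))
    expect_true(all(v >= 0 & v <= 1))
  }
  ht <- asPixelVector(getLayer(traits, "hydraulic_type"))
  expect_true(all(ht %in% 1:4))
  # coarse blocks are constant after nearest upsampling
  ks <- getLayer(traits, "Ks")
  expect_equal(length(unique(as.vector(ks))), 4)   # 2x2 coarse blocks
  expect_error(simulateTraits(truth, coarseFactor = 5), "divisor")
})

test_that("WUI growth calibration reproduces the zone and total changes", {
  g <- gridDef(20, 20)
  set.seed(60)
  pws <- runif(400, 0, 2)
  hz <- classifyHazard(pws, grid = g)
  w <- simulateWui(hz, seed = 60)
  out <- wuiExposure(w$wuiMask, w$pop1990, w$pop2010, hz)
  expect_equal(out["total", "pop1990"], 1e7, tolerance = 1e-9)
  expect_equal(out["total", "pctChange"], 108)
  expect_equal(out[1:3, "pctChange"], c(107, 95, 160))
  expect_equal(out["high", "share1990"], 0.097, tolerance = 1e-9)
  # unit growth with no jitter freezes every zone
  frozen <- simulateWui(hz, growthByZone = c(low = 1, medium = 1, high = 1),
                        seed = 61)
  outF <- wuiExposure(frozen$wuiMask, frozen$pop1990, frozen$pop2010, hz)
  expect_equal(outF$pctChange, rep(0, 4))
  expect_error(simulateWui(hz, growthByZone = c(low = -1, medium = 1, high = 1)),
               ">= 0")
})
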