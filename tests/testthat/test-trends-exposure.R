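test_that("trend estimation is exact on linear and constant inputs", {
  g <- gridDef(1, 3)
  years <- 1980:2020
  vals <- rbind(10 + 0.05 * (years - 1980),   # exact linear rise
                rep(8, length(years)),        # constant
                5 + 0.1 * (years - 1980))
  tm <- vpdTrendMap(annualGridSeries(g, years, vals, units = "hPa"))
  expect_equal(trendValues(tm), c(0.05, 0, 0.1), tolerance = 1e-12)
  expect_equal(trendValues(tm, relative = TRUE)[2], 0)
  expect_equal(tm@meanValue[2], 8)
  expect_equal(trendValues(tm, relative = TRUE)[1], 0.05 / mean(vals[1, ]))
})

test_that("trend matches the hand OLS formula on short series", {
  g <- gridDef(1, 1)
  # hand-computed 5-year series
  tm <- vpdTrendMap(annualGridSeries(g, 2001:2005, matrix(c(10, 11, 10, 12, 12), 1)),
                    minYears = 5)
  expect_equal(trendValues(tm), 0.5)
  # all 3-point series equal the closed form
  set.seed(41)
  for (i in 1:25) {
    y <- rnorm(3); x <- 2001:2003
    tm3 <- vpdTrendMap(annualGridSeries(g, x, matrix(y, 1)), minYears = 3)
    expect_equal(trendValues(tm3),
                 sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
  }
  # insufficient years -> masked
  tooFew <- vpdTrendMap(annualGridSeries(g, 2001:2005, matrix(rnorm(5), 1)),
                        minYears = 10)
  expect_true(is.na(trendValues(tooFew)))
})

test_that("double-hazard fractions match the independence and comonotone limits", {
  set.seed(42)
  n <- 10000
  g <- gridDef(100, 100)
  pm <- new("PWSMap", grid = g, pws = runif(n, 0, 2), r2 = rep(1, n),
            nObs = rep(60L, n), zeroFraction = rep(0, n), valid = rep(TRUE, n))
  indep <- new("TrendMap", grid = g, trend = rnorm(n, 0.05, 0.02),
               relTrend = rep(0.005, n), meanValue = rep(10, n),
               nYears = rep(41L, n))
  dh <- doubleHazard(pm, indep)
  expect_equal(dh$fraction, 0.25, tolerance = 0.05)
  # perfectly rank-correlated fields: joint fraction near one half
  mono <- indep
  mono@trend <- sort(mono@trend)[rank(pm@pws, ties.method = "first")]
  dh2 <- doubleHazard(pm, mono)
  expect_equal(dh2$fraction, 0.5, tolerance = 0.01)
  # high-PWS criterion with no high-PWS pixels is all-false
  low <- pm; low@pws <- runif(n, 0, 1.2)
  dh3 <- doubleHazard(low, indep, criterion = "high_pws_above_avg")
  expect_false(any(dh3$mask, na.rm = TRUE))
  expect_equal(dh3$fraction, 0)
  # no joint support errors
  none <- pm; none@pws[] <- NA; none@valid[] <- FALSE
  expect_error(doubleHazard(none, indep), "jointly valid")
})

test_that("WUI exposure accounting conserves people and reports shares", {
  g <- gridDef(2, 3)
  hz <- classifyHazard(c(0.5, 0.5, 1.2, 1.2, 1.8, 1.8), grid = g)
  wui <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  p1 <- c(4, 2, 3, 0, 1, 99)   # pixel 6 outside the WUI never counts
  # doubling the population doubles every zone: +100% each
  out <- wuiExposure(wui, p1, 2 * p1, hz)
  expect_equal(out$pctChange, rep(100, 4))
  expect_equal(out["total", "pop1990"], 10)
  expect_equal(sum(out[1:3, "share1990"]), 1, tolerance = 1e-9)
  expect_equal(sum(out[1:3, "share2010"]), 1, tolerance = 1e-9)
  # totals 10 -> 20.8 million give a 108% rise
  p2 <- p1 / sum(p1[wui]) * 10e6
  p2[6] <- 0
  out2 <- wuiExposure(wui, p2, p2 / 10e6 * 20.8e6, hz)
  expect_equal(out2["total", "pctChange"], 108)
  # moving one person between zones preserves the total
  moved <- p1; moved[1] <- moved[1] - 1; moved[5] <- moved[5] + 1
  out3 <- wuiExposure(wui, moved, 2 * p1, hz)
  expect_equal(out3["total", "pop1990"], 10)
  # a zone with zero base population is flagged, not infinite
  zeroMed <- c(4, 2, 0, 0, 1, 0)
  out4 <- wuiExposure(wui, zeroMed, 2 * zeroMed, hz)
  expect_true(is.na(out4["medium", "pctChange"]))
  expect_identical(out4["medium", "flag"], "zero_base")
  expect_error(wuiExposure(wui, -p1, p1, hz), "non-negative")
})

test_that("confounder screen reproduces exact and null correlations", {
  set.seed(43)
  n <- 200
  g <- gridDef(10, 20)
  pws <- runif(n, 0, 2)
  pm <- new("PWSMap", grid = g, pws = pws, r2 = rep(1, n), nObs = rep(60L, n),
            zeroFraction = rep(0, n), valid = rep(TRUE, n))
  rep <- confounderScreen(pm, list(self = pws, neg = -pws,
                                   perm = sample(pws), flat = rep(1, n)))
  expect_equal(rep$r2[rep$covariate == "self"], 1)
  expect_equal(rep$r[rep$covariate == "neg"], -1)
  expect_lt(rep$r2[rep$covariate == "perm"], 0.05)
  expect_identical(rep$flag[rep$covariate == "flat"], "constant")
  expect_true(is.na(rep$r[rep$covariate == "flat"]))
  small <- confounderScreen(pm, list(tiny = c(pws[1:10], rep(NA, n - 10))))
  expect_identical(small$flag, "insufficient_n")
})

test_that("NDVI-precipitation sensitivity screens fuel-growth confounding", {
  set.seed(44)
  n <- 150; yrs <- 8
  g <- gridDef(10, 15)
  pws <- runif(n, 0, 2)
  pm <- new("PWSMap", grid = g, pws = pws, r2 = rep(1, n), nObs = rep(60L, n),
            zeroFraction = rep(0, n), valid = rep(TRUE, n))
  precip <- matrix(rgamma(n * yrs, 4, 0.02), n, yrs)
  lc <- rep(1:3, length.out = n)
  # null: NDVI independent of precipitation -> slopes centre on 0, weak r
  ndviNull <- matrix(rnorm(n * yrs, 0.5, 0.05), n, yrs)
  repNull <- ndviPrecipSensitivity(ndviNull, precip, lc, pm)
  slopes <- attr(repNull, "pixelSlopes")
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(n))
  expect_true(all(abs(repNull$r) < 0.35))
  # exact uniform response: slopes all 0.001, flagged constant
  ndviExact <- 0.001 * precip
  repExact <- ndviPrecipSensitivity(ndviExact, precip, lc, pm)
  expect_equal(unique(round(attr(repExact, "pixelSlopes"), 12)), 0.001)
  expect_true(all(repExact$flag == "constant_slope"))
  # slope built anticorrelated with PWS -> negative reported correlation
  gain <- 0.002 * (2 - pws)
  ndviAnti <- gain * precip + matrix(rnorm(n * yrs, 0, 0.01), n, yrs)
  repAnti <- ndviPrecipSensitivity(ndviAnti, precip, lc, pm)
  expect_true(all(repAnti$r < 0))
  # grouping by mean precipitation yields one row per group and land cover
  repGrp <- ndviPrecipSensitivity(ndviAnti, precip, lc, pm, precipGroups = 2)
  expect_equal(nrow(repGrp), 6)
})
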