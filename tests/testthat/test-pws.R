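makeSmallWorld <- function(seed = 5, nRow = 4, nCol = 4, noiseSd = 0,
                           years = 2015:2020, ...) {
  g <- gridDef(nRow, nCol)
  truth <- syntheticTruth(g, seed = seed)
  clim <- simulateClimate(g, years, seed = seed)
  lfmc <- simulateLfmc(clim$dfmc, truth, noiseSd = noiseSd, seed = seed, ...)
  list(grid = g, truth = truth, clim = clim, lfmc = lfmc)
}

test_that("the lag design has one row per gap-free seasonal epoch and lagged columns", {
  w <- makeSmallWorld()
  cfg <- lagConfig()
  an <- anomaly(w$lfmc, seasonalClimatology(w$lfmc, cfg@years))
  dn <- anomaly(w$clim$dfmc, seasonalClimatology(w$clim$dfmc, cfg@years))
  d <- buildLagDesign(an, dn, cfg, pixel = 1)
  expect_equal(dim(d$X), c(60L, 11L))  # 5 years x 12 Jun-Nov epochs
  # lag-0 column is the concurrent predictor anomaly
  expect_equal(d$X[, 1], dn@values[1, d$epochs])
  # column i is the predictor anomaly i-1 epoch steps earlier
  expect_equal(d$X[, 11], dn@values[1, d$epochs - 10L])
  # a missing response epoch deletes exactly that row
  lfmc2 <- w$lfmc
  lfmc2@values[1, d$epochs[4]] <- NA
  an2 <- anomaly(lfmc2, seasonalClimatology(lfmc2, cfg@years))
  d2 <- buildLagDesign(an2, dn, cfg, pixel = 1)
  expect_equal(nrow(d2$X), 59L)
  expect_false(d$epochs[4] %in% d2$epochs)
})

test_that("noise-free synthetic pixels are recovered exactly", {
  w <- makeSmallWorld(nRow = 8, nCol = 8)
  pm <- estimatePwsMap(w$lfmc, w$clim$dfmc, lagConfig())
  expect_true(all(validMask(pm)))
  expect_lt(max(abs(pwsValues(pm) - truePws(w$truth))), 1e-6)
  expect_true(all(fitR2(pm)[validMask(pm)] > 0.999))
})

test_that("a zero kernel yields near-zero estimated PWS", {
  # low-noise null: LFMC anomalies carry no DFMC signal, so any estimated
  # PWS is pure constraint-truncated noise and must stay near zero
  g <- gridDef(5, 5)
  truth <- syntheticTruth(g, seed = 9)
  truth@kernels[] <- 0
  truth@pws <- rowSums(truth@kernels)
  clim <- simulateClimate(g, 2015:2020, seed = 9)
  lfmc <- simulateLfmc(clim$dfmc, truth, noiseSd = 0.3, seed = 9)
  pm <- estimatePwsMap(lfmc, clim$dfmc, lagConfig())
  expect_lt(mean(pwsValues(pm)[validMask(pm)]), 0.05)
})

test_that("PWS is scale-equivariant and shift-invariant", {
  w <- makeSmallWorld(seed = 6)
  cfg <- lagConfig()
  base <- pwsValues(estimatePwsMap(w$lfmc, w$clim$dfmc, cfg))
  scaleSeries <- function(es, f) { es@values <- es@values * f; es }
  shiftSeries <- function(es, c) { es@values <- es@values + c; es }
  # LFMC x 3 -> PWS x 3
  up <- pwsValues(estimatePwsMap(scaleSeries(w$lfmc, 3), w$clim$dfmc, cfg))
  expect_equal(up, 3 * base, tolerance = 1e-8)
  # DFMC x 2 -> PWS / 2
  half <- pwsValues(estimatePwsMap(w$lfmc, scaleSeries(w$clim$dfmc, 2), cfg))
  expect_equal(half, base / 2, tolerance = 1e-8)
  # adding constants to the raw series (climatologies recomputed) changes nothing
  sh <- pwsValues(estimatePwsMap(shiftSeries(w$lfmc, 40),
                                 shiftSeries(w$clim$dfmc, -7), cfg))
  expect_equal(sh, base, tolerance = 1e-10)
})

test_that("anticorrelated predictors are suppressed by the constraint", {
  # flipping the predictor sign anticorrelates every lag with the response;
  # the constraint zeroes the dominant relation, leaving only small
  # chance-positive partial correlations among the 11 lagged columns
  w <- makeSmallWorld(seed = 7)
  cfg <- lagConfig()
  flipped <- w$clim$dfmc
  flipped@values <- -flipped@values
  pm <- estimatePwsMap(w$lfmc, flipped, cfg)
  base <- estimatePwsMap(w$lfmc, w$clim$dfmc, cfg)
  expect_true(all(pwsValues(pm)[validMask(pm)] >= 0))
  expect_lt(mean(pwsValues(pm)[validMask(pm)]),
            0.15 * mean(pwsValues(base)[validMask(base)]))
})

test_that("the 50%-missing rule and row minimum mask pixels", {
  w <- makeSmallWorld(seed = 8)
  cfg <- lagConfig()
  cal <- calendarOf(w$lfmc)
  seasonCols <- which(cal$year %in% cfg@years & cal$month %in% cfg@seasonMonths)
  # kill 60% of pixel 1's seasonal record -> masked
  kill <- seasonCols[seq_len(ceiling(0.6 * length(seasonCols)))]
  w$lfmc@values[1, kill] <- NA
  pm <- estimatePwsMap(w$lfmc, w$clim$dfmc, cfg)
  expect_false(validMask(pm)[1])
  expect_true(is.na(pwsValues(pm)[1]))
  expect_true(all(validMask(pm)[-1]))
  # an entirely missing response gives an empty map with a warning
  w$lfmc@values[] <- NA
  expect_warning(pm2 <- estimatePwsMap(w$lfmc, w$clim$dfmc, cfg), "no valid pixels")
  expect_false(any(validMask(pm2)))
})

test_that("modified PWS (VPD predictor) is weakly related to standard PWS", {
  w <- makeSmallWorld(seed = 10, nRow = 10, nCol = 10, noiseSd = NULL)
  cfg <- lagConfig()
  std <- estimatePwsMap(w$lfmc, w$clim$dfmc, cfg)
  mod <- estimatePwsMap(w$lfmc, w$clim$vpd, cfg)
  ok <- validMask(std) & validMask(mod)
  r2 <- cor(pwsValues(std)[ok], pwsValues(mod)[ok])^2
  expect_lt(r2, 0.5)
  # while the standard PWS still tracks the truth closely
  expect_gt(cor(pwsValues(std)[ok], truePws(w$truth)[ok]), 0.8)
})

test_that("LagFit accessors and zero fraction behave", {
  set.seed(13)
  X <- matrix(rnorm(200), 50, 4)
  y <- drop(X %*% c(1, 0, 0.5, 0)) + rnorm(50, sd = 0.1)
  fit <- fitNonnegLagRegression(y, X)
  expect_equal(pwsFromFit(fit), sum(fit@beta))
  expect_equal(fit@zeroFraction, mean(fit@beta == 0))
  expect_true(fit@r2 > 0.9)
})
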