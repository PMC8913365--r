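test_that("the half-monthly calendar tiles each year into 24 epochs", {
  cal <- epochCalendar(2016:2017)
  expect_equal(nrow(cal), 48)
  expect_equal(as.integer(table(cal$year)), c(24L, 24L))
  expect_true(all(diff(as.numeric(cal$start)) > 0))
  # epochs within a year are gapless and cover every day
  expect_equal(sum(cal$days[cal$year == 2016]), 366)  # leap year
  expect_equal(sum(cal$days[cal$year == 2017]), 365)
  expect_true(all(cal$start[-1] == cal$end[-nrow(cal)] + 1))
  expect_equal(cal$month, rep(rep(1:12, each = 2), 2))
})

test_that("epoch compositing averages days and handles gaps", {
  g <- gridDef(1, 1, dx = 1, dy = 1)
  cal <- epochCalendar(2019)
  dates <- seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = "day")
  # constant daily series
  es <- epochComposite(rep(12, length(dates)), dates, cal, g)
  expect_true(all(gridValues(es) == 12))
  # 0s for days 1-15 of June, 10s for days 16-30
  v <- rep(NA_real_, length(dates))
  v[format(dates, "%m") == "06"] <- rep(c(0, 10), c(15, 15))
  es2 <- epochComposite(v, dates, cal, g)
  juneCols <- which(cal$month == 6)
  expect_equal(as.numeric(gridValues(es2)[, juneCols]), c(0, 10))
  # a single valid day defines its epoch; empty epochs are NA
  v3 <- rep(NA_real_, length(dates)); v3[20] <- 42
  es3 <- epochComposite(v3, dates, cal, g)
  expect_equal(as.numeric(gridValues(es3)[, 2]), 42)
  expect_true(all(is.na(gridValues(es3)[, -2])))
  # calendar outside the data span errors with the missing range
  expect_error(epochComposite(v3, dates, epochCalendar(2018:2019), g),
               "does not cover")
})

test_that("seasonal climatology averages years and enforces minYears", {
  g <- gridDef(1, 2, dx = 1, dy = 1)
  cal <- epochCalendar(2016:2017)
  vals <- matrix(rep(c(10, 20), each = 2 * 24)[1:(2 * 48)], 2, 48)
  vals[, cal$year == 2016] <- 10
  vals[, cal$year == 2017] <- 20
  clim <- seasonalClimatology(epochSeries(g, vals, cal))
  expect_true(all(gridValues(clim) == 15))
  # identical values every year: climatology equals any year
  same <- matrix(rep(sin(1:24), 2), 2, 48, byrow = TRUE)
  clim2 <- seasonalClimatology(epochSeries(g, same, cal))
  expect_equal(gridValues(clim2)[1, ], sin(1:24))
  # one contributing year with minYears = 2 is masked
  gap <- same; gap[1, cal$year == 2017] <- NA
  clim3 <- seasonalClimatology(epochSeries(g, gap, cal), minYears = 2)
  expect_true(all(is.na(gridValues(clim3)[1, ])))
  expect_false(anyNA(gridValues(clim3)[2, ]))
  expect_error(seasonalClimatology(epochSeries(g, same, cal), years = integer(0)),
               "empty year set")
})

test_that("climatology of sinusoid plus noise converges at rate 1/sqrt(years)", {
  set.seed(11)
  g <- gridDef(1, 1, dx = 1, dy = 1)
  cal <- epochCalendar(2016:2020)
  truthCycle <- 5 * sin(2 * pi * (1:24) / 24)
  noiseSd <- 1
  vals <- matrix(truthCycle[cal$eoy] + rnorm(nrow(cal), sd = noiseSd), 1)
  clim <- seasonalClimatology(epochSeries(g, vals, cal))
  err <- gridValues(clim)[1, ] - truthCycle
  expect_lt(max(abs(err)), 4 * noiseSd / sqrt(5))
})

test_that("anomalies satisfy the defining identities", {
  set.seed(12)
  g <- gridDef(2, 2, dx = 1, dy = 1)
  cal <- epochCalendar(2016:2019)
  vals <- matrix(rnorm(4 * nrow(cal), mean = 100, sd = 10), 4)
  es <- epochSeries(g, vals, cal)
  clim <- seasonalClimatology(es)
  an <- anomaly(es, clim)
  # per (pixel, epoch-of-year) anomalies over the climatology years sum to 0
  for (e in c(1, 13, 24)) {
    cols <- which(cal$eoy == e)
    expect_lt(max(abs(rowSums(gridValues(an)[, cols]))), 1e-9)
  }
  # series equal to its climatology -> all-zero anomalies
  rep4 <- gridValues(clim)[, cal$eoy]
  zero <- anomaly(epochSeries(g, rep4, cal), clim)
  expect_true(all(abs(gridValues(zero)) < 1e-12))
  # constant shift against a FIXED climatology moves anomalies by c ...
  shifted <- epochSeries(g, vals + 5, cal)
  expect_equal(gridValues(anomaly(shifted, clim)), gridValues(an) + 5)
  # ... and is absorbed when the climatology is recomputed
  an2 <- anomaly(shifted, seasonalClimatology(shifted))
  expect_equal(gridValues(an2), gridValues(an), tolerance = 1e-12)
})

test_that("fire years run April-March and drop incomplete years", {
  # monthly inputs: March 2002 belongs to fire year 2001
  expect_equal(fireYearLabel(2002, 3), 2001)
  expect_equal(fireYearLabel(2002, 4), 2002)
  months <- expand.grid(month = 1:12, year = 2001:2003)
  ba <- rep(0, nrow(months)); ba[months$year == 2002 & months$month == 3] <- 5
  agg <- monthlyFireYearAggregate(ba, months$year, months$month, stat = "sum")
  expect_equal(agg$years, c(2001L, 2002L))  # 2000 and 2003 are incomplete
  expect_equal(as.numeric(agg$values), c(5, 0))
  # monthly BA of 1 km2 sums to 12; constant VPD averages to itself
  one <- rep(1, nrow(months))
  expect_true(all(monthlyFireYearAggregate(one, months$year, months$month, stat = "sum")$values == 12))
  expect_true(all(monthlyFireYearAggregate(one * 10, months$year, months$month, stat = "mean")$values == 10))

  # epoch-series route agrees
  g <- gridDef(1, 1, dx = 1, dy = 1)
  cal <- epochCalendar(2001:2003)
  es <- epochSeries(g, matrix(1, 1, nrow(cal)), cal, units = "km2")
  fy <- fireYearAggregate(es, 4, "sum")
  expect_equal(fy@years, c(2001L, 2002L))
  expect_true(all(gridValues(fy) == 24))
  short <- epochSeries(g, matrix(1, 1, 24), epochCalendar(2001), units = "km2")
  expect_warning(fireYearAggregate(short, 4, "sum"), "no complete fire year")
})
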