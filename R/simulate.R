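## Synthetic gridded fixtures with a recorded ground truth. The generators
## reproduce the statistical structure each analysis stage assumes --
## seasonal cycles plus AR(1) anomalies for the climate drivers, live fuel
## moisture as a known non-negative lag-kernel convolution of dead fuel
## moisture anomalies, burned area with a per-pixel VPD slope that is affine
## in PWS, traits correlated with block-averaged PWS at coarser resolution,
## and WUI populations with hazard-dependent growth -- so every stage can be
## validated by parameter recovery with no external data.

defaultTraitNames <- c("Ks", "n", "porosity", "sand", "silt", "clay",
                       "canopy_height", "capacitance", "g1",
                       "max_xylem_conductance", "psi50", "hydraulic_type",
                       "isohydricity", "root_depth")

#' Default trait-effect coefficients
#'
#' Named vector of 14 trait effects on block-averaged PWS; the default makes
#' saturated soil conductivity the dominant driver with two weaker soil /
#' rooting effects, mirroring the expectation that soil hydraulics lead the
#' attribution.
#' @return named numeric vector of length 14.
#' @export
defaultTraitEffects <- function() {
  eff <- setNames(numeric(14), defaultTraitNames)
  eff["Ks"] <- 1
  eff["n"] <- 0.6
  eff["root_depth"] <- 0.4
  eff
}

smoothField <- function(grid, seed, coarse = 8) {
  ## smooth standard-normal-ish field: coarse white noise, bilinear upsample
  set.seed(seed)
  cr <- max(2L, min(coarse, grid@nRow))
  cc <- max(2L, min(coarse, grid@nCol))
  cg <- gridDef(cr, cc, x0 = grid@x0, y0 = grid@y0,
                dx = grid@nCol * grid@dx / cc, dy = grid@nRow * grid@dy / cr)
  base <- matrix(rnorm(cr * cc), cr, cc)
  fine <- regridMatrix(base, cg, grid, "bilinear")
  asPixelVector(fine) + rnorm(nPixels(grid), sd = 0.3)
}

#' Create a synthetic truth record
#'
#' Draws per-pixel non-negative lag kernels as sparse exponentials (each of
#' the 11 lags active with probability 1/2, weights decaying with lag) and
#' scales them so the kernel sums -- the true PWS -- follow a spatially
#' smooth field mapped to a uniform distribution over `pwsRange`.
#'
#' @param grid the [GridDef-class].
#' @param seed master seed.
#' @param nLagTerms number of lag terms (default 11: lags 0-150 d by 15 d).
#' @param pwsRange range of true PWS (default `c(0, 2)`).
#' @param a,b slope law `d(BA)/d(VPD) = a + b * PWS` at the 15-bin
#'   aggregation scale; defaults `a = 350`, `b = 175` km2 hPa-1 span
#'   350-700 over the PWS range.
#' @param traitEffects named numeric vector of 14 trait effects (default
#'   [defaultTraitEffects()]).
#' @return A [SyntheticTruth-class].
#' @export
syntheticTruth <- function(grid, seed = 42, nLagTerms = 11, pwsRange = c(0, 2),
                           a = 350, b = 175, traitEffects = defaultTraitEffects()) {
  n <- nPixels(grid)
  pwsField <- smoothField(grid, seed)
  set.seed(seed + 1L)
  ## rank-transform to uniform over pwsRange, preserving spatial smoothness
  pws <- pwsRange[1] + diff(pwsRange) * (rank(pwsField, ties.method = "first") - 0.5) / n
  decay <- runif(n, 0.1, 0.8)
  active <- matrix(runif(n * nLagTerms) < 0.5, n, nLagTerms)
  noActive <- rowSums(active) == 0L
  active[cbind(which(noActive), sample.int(nLagTerms, sum(noActive), replace = TRUE))] <- TRUE
  shape <- exp(-outer(decay, 0:(nLagTerms - 1))) * active
  kernels <- shape * (pws / rowSums(shape))
  stopifnot(length(traitEffects) == 14)
  if (is.null(names(traitEffects))) names(traitEffects) <- defaultTraitNames
  new("SyntheticTruth", grid = grid, kernels = kernels, pws = rowSums(kernels),
      slopeLaw = c(a = unname(a), b = unname(b)), traitEffects = traitEffects,
      seed = as.integer(seed))
}

arOneSeries <- function(nPix, nT, rho, sdMarg) {
  innov <- matrix(rnorm(nPix * nT, sd = sdMarg * sqrt(1 - rho^2)), nPix, nT)
  out <- matrix(0, nPix, nT)
  out[, 1] <- rnorm(nPix, sd = sdMarg)
  for (t in 2:nT) out[, t] <- rho * out[, t - 1] + innov[, t]
  out
}

#' Simulate the climate drivers
#'
#' Dead fuel moisture (DFMC, %), vapour pressure deficit (VPD, hPa) and
#' epoch precipitation totals (mm) on the half-monthly calendar: each is a
#' pixel-specific seasonal cycle plus AR(1) anomalies. VPD anomalies share a
#' configurable (anticorrelated) component with DFMC anomalies plus a
#' common interannual term, and can carry a per-pixel linear trend.
#'
#' @param grid the [GridDef-class].
#' @param years calendar years to simulate (>= 6 years leaves lag spin-up
#'   before a 5-year regression record).
#' @param seed integer seed; the output is bit-reproducible given
#'   (arguments, seed).
#' @param ar1 lag-1 autocorrelation of the epoch anomalies (default 0.7).
#' @param dfmcAnomSd,vpdAnomSd marginal anomaly standard deviations
#'   (default 2.5 % and 1.2 hPa); zero gives a pure seasonal cycle.
#' @param sharedFrac weight of the DFMC-opposing shared component in VPD
#'   anomalies, in [0, 1) (default 0.4).
#' @param vpdYearSd standard deviation of the common annual VPD offset
#'   (hPa; default 1).
#' @param vpdTrend per-pixel VPD trend in hPa yr-1 (scalar or vector;
#'   default 0).
#' @return list of [EpochSeries-class]: `dfmc`, `vpd`, `precip`.
#' @export
simulateClimate <- function(grid, years, seed = 42, ar1 = 0.7,
                            dfmcAnomSd = 2.5, vpdAnomSd = 1.2,
                            sharedFrac = 0.4, vpdYearSd = 1, vpdTrend = 0) {
  if (dfmcAnomSd < 0 || vpdAnomSd < 0) stop("anomaly variances must be non-negative")
  if (sharedFrac < 0 || sharedFrac >= 1) stop("sharedFrac must be in [0, 1)")
  cal <- epochCalendar(years)
  nT <- nrow(cal); n <- nPixels(grid)
  set.seed(seed)
  dfmcMean <- 15 + 2 * smoothField(grid, seed + 11L)
  vpdMean <- 12 + 1.5 * smoothField(grid, seed + 12L)
  set.seed(seed + 1L)
  seasonal <- cos(2 * pi * (cal$eoy - 14) / 24)  # +1 mid-July
  dfmcSeas <- outer(dfmcMean, -6 * seasonal, function(m, s) m + s)
  vpdSeas <- outer(vpdMean, 5 * seasonal, function(m, s) m + s)
  dfmcAnom <- arOneSeries(n, nT, ar1, dfmcAnomSd)
  vpdOwn <- arOneSeries(n, nT, ar1, 1)
  sharedTerm <- if (dfmcAnomSd > 0) -sharedFrac * dfmcAnom / dfmcAnomSd else 0
  vpdAnom <- vpdAnomSd * (sharedTerm + sqrt(1 - sharedFrac^2) * vpdOwn)
  yearOffset <- setNames(rnorm(length(unique(cal$year)), sd = vpdYearSd),
                         sort(unique(cal$year)))
  vpdAnom <- vpdAnom + matrix(yearOffset[as.character(cal$year)], n, nT, byrow = TRUE)
  trendTerm <- outer(rep_len(vpdTrend, n), cal$year - min(cal$year))
  precipSeasMean <- 40 + 30 * cos(2 * pi * (cal$eoy - 1) / 24)  # winter peak
  precip <- matrix(rgamma(n * nT, shape = 2,
                          scale = rep(precipSeasMean / 2, each = n)), n, nT)
  list(dfmc = epochSeries(grid, dfmcSeas + dfmcAnom, cal, units = "%"),
       vpd = epochSeries(grid, vpdSeas + vpdAnom + trendTerm, cal, units = "hPa"),
       precip = epochSeries(grid, precip, cal, units = "mm"))
}

#' Simulate live fuel moisture from DFMC and a truth record
#'
#' Runs the distributed-lag model forward: LFMC is a pixel-specific
#' seasonal cycle plus the kernel convolution of DFMC anomalies plus
#' Gaussian noise. With `targetR2` set (and `noiseSd = NULL`), the
#' per-pixel noise standard deviation is chosen from the signal variance so
#' the population R2 of the generating regression equals `targetR2` --
#' the study-condition calibration for a median fit R2 near 0.3. The first
#' `nLagTerms - 1` epochs have no full lag history and are missing.
#'
#' @param dfmc DFMC [EpochSeries-class].
#' @param truth a [SyntheticTruth-class] (kernel length must match 11 lag
#'   terms).
#' @param noiseSd scalar noise standard deviation (%), or `NULL` to
#'   calibrate from `targetR2`.
#' @param targetR2 target in-sample fit R2 of the estimating regression
#'   when `noiseSd` is `NULL` (default 0.3). Because a regression with
#'   `effParams` effective free parameters on `regRows` rows inflates the
#'   in-sample R2, the generating signal-to-total variance ratio is set to
#'   `1 - (1 - targetR2) * (regRows - 1) / (regRows - 1 - effParams)`.
#' @param regRows nominal regression rows of the downstream fit (default
#'   60: five years of twelve June-November epochs).
#' @param effParams effective free parameters of the constrained fit
#'   (default 7: about half of the 11 non-negative slopes active, plus the
#'   intercept).
#' @param missingFrac fraction of epoch values knocked out at random
#'   (default 0).
#' @param seed integer seed.
#' @return An [EpochSeries-class] of LFMC (%).
#' @export
simulateLfmc <- function(dfmc, truth, noiseSd = NULL, targetR2 = 0.3,
                         missingFrac = 0, seed = 42, regRows = 60, effParams = 7) {
  stopifnot(sameGrid(gridOf(dfmc), gridOf(truth)))
  nl <- ncol(truth@kernels)
  if (nl != 11L) stop("kernel length must be 11 (lags 0-150 d in 15 d steps)")
  anom <- anomaly(dfmc, seasonalClimatology(dfmc, minYears = 1))@values
  n <- nrow(anom); nT <- ncol(anom)
  signal <- matrix(NA_real_, n, nT)
  tIdx <- nl:nT
  acc <- matrix(0, n, length(tIdx))
  for (i in seq_len(nl)) acc <- acc + truth@kernels[, i] * anom[, tIdx - (i - 1L), drop = FALSE]
  signal[, tIdx] <- acc
  set.seed(seed + 2L)
  if (is.null(noiseSd)) {
    if (targetR2 <= 0 || targetR2 > 1) stop("targetR2 must be in (0, 1]")
    rho2 <- 1 - (1 - targetR2) * (regRows - 1) / (regRows - 1 - effParams)
    if (rho2 <= 0) stop("targetR2 too small for the finite-sample adjustment")
    sigSd <- apply(signal[, tIdx, drop = FALSE], 1, sd)
    sdVec <- sigSd * sqrt((1 - rho2) / rho2)
  } else sdVec <- rep_len(noiseSd, n)
  noise <- matrix(rnorm(n * nT), n, nT) * sdVec
  set.seed(seed + 3L)
  lfmcMean <- 100 + 10 * smoothField(grid = gridOf(dfmc), seed = seed + 4L)
  seasonal <- -25 * cos(2 * pi * (dfmc@calendar$eoy - 14) / 24)  # summer minimum
  vals <- outer(lfmcMean, rep(1, nT)) +
    matrix(seasonal, n, nT, byrow = TRUE) + signal + noise
  vals[, seq_len(nl - 1L)] <- NA_real_
  if (missingFrac > 0) {
    set.seed(seed + 5L)
    vals[matrix(runif(n * nT) < missingFrac, n, nT)] <- NA_real_
  }
  epochSeries(gridOf(dfmc), vals, dfmc@calendar, units = "%")
}

#' Simulate burned area under an affine PWS slope law
#'
#' Per pixel and fire year, expected burned area is
#' `(a + b * PWS) * VPD / areaNorm` (clipped at zero after adding Gaussian
#' noise), so pooling `areaNorm` pixels into a bin yields a burned-area-vs-
#' VPD slope of about `a + b * meanPWS`. The default `areaNorm` of one
#' fifteenth of the pixels anchors the law at the standard 15-bin
#' aggregation scale.
#'
#' @param truth a [SyntheticTruth-class] (provides PWS and the `a`, `b`
#'   law).
#' @param vpdAnnual per-pixel fire-year VPD [AnnualGridSeries-class] (hPa).
#' @param areaNorm pixels per reference bin (default `nPixels / 15`).
#' @param baNoiseSd per pixel-year burned-area noise (km2, default 1).
#' @param alpha per-pixel baseline offset (km2, default 0).
#' @param seed integer seed.
#' @return An [AnnualGridSeries-class] of burned area (km2). Warns if the
#'   expected (pre-noise) burned area is negative anywhere.
#' @export
simulateFire <- function(truth, vpdAnnual, areaNorm = NULL, baNoiseSd = 1,
                         alpha = 0, seed = 42) {
  stopifnot(sameGrid(gridOf(truth), gridOf(vpdAnnual)))
  n <- nPixels(gridOf(truth))
  if (is.null(areaNorm)) areaNorm <- n / 15
  a <- truth@slopeLaw["a"]; b <- truth@slopeLaw["b"]
  expect <- alpha + (a + b * truth@pws) * vpdAnnual@values / areaNorm
  if (any(expect < 0, na.rm = TRUE))
    warning("expected burned area is negative before clipping; slope law and VPD range disagree")
  set.seed(seed + 6L)
  ba <- pmax(expect + matrix(rnorm(length(expect), sd = baNoiseSd),
                             nrow(expect), ncol(expect)), 0)
  annualGridSeries(gridOf(truth), vpdAnnual@years, ba, units = "km2")
}

#' Simulate plant and soil hydraulic trait rasters
#'
#' Traits are generated at a coarser resolution as linear-plus-noise
#' functions of block-averaged true PWS (standardised), then
#' nearest-neighbour upsampled to the analysis grid -- mimicking 25-km
#' trait products against a 4-km PWS map. Sand/silt/clay are squashed into
#' [0, 1]; the hydraulic functional type is an integer code from quartiles
#' of its latent value.
#'
#' @param truth a [SyntheticTruth-class] (provides PWS and trait effects).
#' @param coarseFactor integer block size of the trait resolution (default
#'   8; 1 keeps the analysis resolution). Must divide the grid shape.
#' @param noiseSd trait noise standard deviation on the standardised scale
#'   (default 0.3).
#' @param seed integer seed.
#' @return A [RasterStack-class] of 14 named trait maps.
#' @export
simulateTraits <- function(truth, coarseFactor = 8, noiseSd = 0.3, seed = 42) {
  g <- gridOf(truth)
  f <- as.integer(coarseFactor)
  if (f < 1 || g@nRow %% f != 0 || g@nCol %% f != 0)
    stop("coarseFactor must be a positive divisor of the grid shape")
  cg <- gridDef(g@nRow %/% f, g@nCol %/% f, pixelArea = g@pixelArea * f^2,
                x0 = g@x0, y0 = g@y0, dx = g@dx * f, dy = g@dy * f)
  pwsCoarse <- blockAggregate(asGridMatrix(truth@pws, g), f, f, "mean")
  z <- as.vector(pwsCoarse)
  z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
  set.seed(seed + 7L)
  eff <- truth@traitEffects
  layers <- lapply(names(eff), function(nm) {
    raw <- eff[[nm]] * z + rnorm(length(z), sd = noiseSd)
    val <- switch(nm,
      sand = , silt = , clay = pmin(1, pmax(0, 0.4 + 0.15 * raw)),
      hydraulic_type = as.numeric(cut(raw, breaks = quantile(raw, 0:4 / 4),
                                      include.lowest = TRUE, labels = FALSE)),
      raw)
    coarseM <- matrix(val, cg@nRow, cg@nCol)
    regridMatrix(coarseM, cg, g, "nearest")
  })
  names(layers) <- names(eff)
  rasterStack(g, layers, units = "mixed")
}

#' Simulate WUI masks and census populations
#'
#' Draws a wildland-urban-interface mask over a fraction of each hazard
#' zone's pixels, distributes the 1990 population lognormally over WUI
#' pixels with fixed zone shares, and grows it to 2010 by zone-specific
#' factors with optional lognormal jitter. The default calibration --
#' 10 million people in 1990 split 55.79/34.51/9.7% across low/medium/high
#' zones with growth factors 2.07/1.95/2.60 -- yields a 108% total rise
#' (10 to 20.8 million) and zone rises of 107/95/160%.
#'
#' @param hazard a [HazardMap-class].
#' @param totalPop1990 total 1990 WUI population (default 1e7).
#' @param growthByZone named growth factors for low/medium/high (default
#'   `c(2.07, 1.95, 2.60)`).
#' @param zoneShares1990 1990 population shares per zone; the default is
#'   the exact split that makes the zone growth factors reproduce a 108%
#'   total rise.
#' @param wuiFrac fraction of each zone's pixels in the WUI (default 0.3).
#' @param jitterSd lognormal sdlog of the per-pixel growth jitter (default
#'   0: exact zone growth).
#' @param seed integer seed.
#' @return list with `wuiMask` (logical per pixel), `pop1990`, `pop2010`
#'   (numeric per pixel, zero outside the WUI).
#' @export
simulateWui <- function(hazard, totalPop1990 = 1e7,
                        growthByZone = c(low = 2.07, medium = 1.95, high = 2.60),
                        zoneShares1990 = c(low = 0.06695 / 0.12,
                                           medium = 0.903 - 0.06695 / 0.12,
                                           high = 0.097),
                        wuiFrac = 0.3, jitterSd = 0, seed = 42) {
  if (any(growthByZone < 0)) stop("growth factors must be >= 0")
  zone <- hazard@zone
  n <- length(zone)
  set.seed(seed + 8L)
  wui <- logical(n)
  pop1990 <- numeric(n)
  for (z in 1:3) {
    idx <- which(!is.na(zone) & zone == z)
    if (!length(idx)) next
    m <- max(1L, round(wuiFrac * length(idx)))
    sel <- if (length(idx) == 1L) idx else sample(idx, m)
    wui[sel] <- TRUE
    draws <- stats::rlnorm(length(sel), meanlog = 0, sdlog = 1)
    pop1990[sel] <- draws / sum(draws) * zoneShares1990[z] * totalPop1990
  }
  jitter <- if (jitterSd > 0)
    exp(rnorm(n, sd = jitterSd) - jitterSd^2 / 2) else rep(1, n)
  pop2010 <- numeric(n)
  ok <- wui & !is.na(zone)
  pop2010[ok] <- pop1990[ok] * growthByZone[zone[ok]] * jitter[ok]
  list(wuiMask = wui, pop1990 = pop1990, pop2010 = pop2010)
}
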