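#' @import methods
#' @importFrom stats coef cor lm median predict pt quantile rgamma rlnorm rnorm runif sd var setNames
#' @importFrom utils read.csv write.csv
NULL

## ---------------------------------------------------------------------------
## Grid definition
## ---------------------------------------------------------------------------

#' Grid definition
#'
#' Describes the common analysis grid: shape, per-pixel area, and a simple
#' top-left / pixel-centre-registered coordinate system. Pixels are indexed
#' row-major: pixel `s` of an `nRow x nCol` grid sits at row
#' `ceiling(s / nCol)`, column `((s - 1) %% nCol) + 1`.
#'
#' @slot nRow,nCol grid shape (rows, columns).
#' @slot pixelArea area of one pixel in km2 (uniform across the grid).
#' @slot x0,y0 map coordinates of the top-left corner of the grid.
#' @slot dx,dy pixel spacing in map units (x increases east, y decreases
#'   south from `y0`).
#' @exportClass GridDef
setClass("GridDef",
  slots = c(nRow = "integer", nCol = "integer", pixelArea = "numeric",
            x0 = "numeric", y0 = "numeric", dx = "numeric", dy = "numeric"))

setValidity("GridDef", function(object) {
  msg <- character()
  if (length(object@nRow) != 1L || object@nRow < 1L) msg <- c(msg, "nRow must be a single count >= 1")
  if (length(object@nCol) != 1L || object@nCol < 1L) msg <- c(msg, "nCol must be a single count >= 1")
  if (length(object@pixelArea) != 1L || !is.finite(object@pixelArea) || object@pixelArea <= 0)
    msg <- c(msg, "pixelArea must be a single positive number")
  if (object@dx <= 0 || object@dy <= 0) msg <- c(msg, "dx and dy must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a grid definition
#'
#' @param nRow,nCol grid shape.
#' @param pixelArea pixel area in km2. Defaults to `dx * dy` so a 4-unit
#'   spacing gives the 16 km2 of a 4-km pixel.
#' @param x0,y0 top-left corner coordinates.
#' @param dx,dy pixel spacing.
#' @return A [GridDef-class] object.
#' @examples
#' g <- gridDef(64, 64)
#' nPixels(g)
#' @export
gridDef <- function(nRow, nCol, pixelArea = dx * dy, x0 = 0, y0 = 0, dx = 4, dy = 4) {
  new("GridDef", nRow = as.integer(nRow), nCol = as.integer(nCol),
      pixelArea = as.numeric(pixelArea), x0 = as.numeric(x0), y0 = as.numeric(y0),
      dx = as.numeric(dx), dy = as.numeric(dy))
}

#' Number of pixels in a grid
#' @param grid a [GridDef-class].
#' @return integer pixel count.
#' @export
nPixels <- function(grid) grid@nRow * grid@nCol

#' Grid shape
#' @param grid a [GridDef-class].
#' @return integer vector `c(nRow, nCol)`.
#' @export
gridDims <- function(grid) c(grid@nRow, grid@nCol)

#' Pixel area of a grid
#' @param grid a [GridDef-class].
#' @return pixel area in km2.
#' @export
pixelArea <- function(grid) grid@pixelArea

setMethod("show", "GridDef", function(object) {
  cat(sprintf("GridDef: %d x %d pixels, %.3g km2/pixel, origin (%g, %g), spacing (%g, %g)\n",
              object@nRow, object@nCol, object@pixelArea,
              object@x0, object@y0, object@dx, object@dy))
})

sameGrid <- function(a, b, tol = 1e-9) {
  a@nRow == b@nRow && a@nCol == b@nCol &&
    abs(a@x0 - b@x0) < tol && abs(a@y0 - b@y0) < tol &&
    abs(a@dx - b@dx) < tol && abs(a@dy - b@dy) < tol
}

## ---------------------------------------------------------------------------
## Raster stack
## ---------------------------------------------------------------------------

#' Stack of named 2-D layers on a common grid
#'
#' @slot grid the [GridDef-class] all layers conform to.
#' @slot layers named list of numeric matrices (`nRow x nCol` each).
#' @slot units single units tag for the stack (e.g. "%", "hPa", "km2", "1").
#' @exportClass RasterStack
setClass("RasterStack",
  slots = c(grid = "GridDef", layers = "list", units = "character"))

setValidity("RasterStack", function(object) {
  msg <- character()
  d <- gridDims(object@grid)
  if (length(object@units) != 1L) msg <- c(msg, "units must be a single tag")
  bad <- !vapply(object@layers, function(m) is.matrix(m) && all(dim(m) == d), logical(1))
  if (any(bad)) msg <- c(msg, sprintf("layers not conforming to the grid: %s",
                                      paste(names(object@layers)[bad], collapse = ", ")))
  if (length(object@layers) && is.null(names(object@layers)))
    msg <- c(msg, "layers must be named")
  if (length(msg)) msg else TRUE
})

#' Construct a raster stack
#' @param grid a [GridDef-class].
#' @param layers named list of matrices conforming to `grid`.
#' @param units units tag applied to every layer.
#' @return A [RasterStack-class].
#' @export
rasterStack <- function(grid, layers, units = "1") {
  new("RasterStack", grid = grid, layers = layers, units = units)
}

#' @describeIn rasterStack layer names of a stack.
#' @param x a [RasterStack-class].
#' @export
layerNames <- function(x) names(x@layers)

#' Extract one layer of a stack as a matrix
#' @param x a [RasterStack-class].
#' @param name layer name or index.
#' @return numeric matrix.
#' @export
getLayer <- function(x, name) x@layers[[name]]

setMethod("show", "RasterStack", function(object) {
  cat(sprintf("RasterStack: %d layer(s) [%s] on %d x %d grid\n",
              length(object@layers), object@units,
              object@grid@nRow, object@grid@nCol))
  if (length(object@layers)) cat("  layers:", paste(utils::head(layerNames(object), 8), collapse = ", "),
                                 if (length(object@layers) > 8) "..." else "", "\n")
})

## ---------------------------------------------------------------------------
## Epoch series and derived containers
## ---------------------------------------------------------------------------

#' Per-pixel values on a half-monthly epoch calendar
#'
#' Values are stored as an `nPixels x nEpochs` matrix; pixels are row-major
#' grid indices, epochs follow the calendar returned by [epochCalendar()].
#'
#' @slot grid the [GridDef-class].
#' @slot values numeric matrix, pixels x epochs; `NA` marks missing data.
#' @slot calendar data frame from [epochCalendar()] (columns `year`, `month`,
#'   `eoy`, `start`, `end`, `days`).
#' @slot units units tag.
#' @exportClass EpochSeries
setClass("EpochSeries",
  slots = c(grid = "GridDef", values = "matrix", calendar = "data.frame",
            units = "character"))

setValidity("EpochSeries", function(object) {
  msg <- character()
  if (nrow(object@values) != nPixels(object@grid))
    msg <- c(msg, "values must have one row per grid pixel")
  if (ncol(object@values) != nrow(object@calendar))
    msg <- c(msg, "values must have one column per calendar epoch")
  need <- c("year", "month", "eoy")
  if (!all(need %in% names(object@calendar)))
    msg <- c(msg, "calendar must carry year, month and eoy columns")
  if (length(msg)) msg else TRUE
})

#' Construct an epoch series
#' @param grid a [GridDef-class].
#' @param values pixels x epochs matrix.
#' @param calendar calendar data frame ([epochCalendar()]).
#' @param units units tag.
#' @return An [EpochSeries-class].
#' @export
epochSeries <- function(grid, values, calendar, units = "1") {
  new("EpochSeries", grid = grid, values = values, calendar = calendar, units = units)
}

#' Anomaly series (value minus epoch-of-year climatology)
#' @exportClass AnomalySeries
setClass("AnomalySeries", contains = "EpochSeries")

#' Seasonal climatology keyed by epoch-of-year
#'
#' @slot grid the [GridDef-class].
#' @slot values pixels x 24 matrix of per-epoch-of-year means.
#' @slot counts pixels x 24 matrix of contributing-year counts.
#' @slot years the years the climatology was computed over.
#' @slot units units tag.
#' @exportClass Climatology
setClass("Climatology",
  slots = c(grid = "GridDef", values = "matrix", counts = "matrix",
            years = "integer", units = "character"))

setValidity("Climatology", function(object) {
  msg <- character()
  if (nrow(object@values) != nPixels(object@grid) || ncol(object@values) != 24L)
    msg <- c(msg, "values must be nPixels x 24")
  if (!all(dim(object@counts) == dim(object@values)))
    msg <- c(msg, "counts must match values in shape")
  if (length(msg)) msg else TRUE
})

#' Per-pixel annual series (fire-year aggregates, annual climate means)
#'
#' @slot grid the [GridDef-class].
#' @slot years integer year labels (fire years are labelled by their starting
#'   calendar year).
#' @slot values pixels x years matrix.
#' @slot units units tag.
#' @exportClass AnnualGridSeries
setClass("AnnualGridSeries",
  slots = c(grid = "GridDef", years = "integer", values = "matrix",
            units = "character"))

setValidity("AnnualGridSeries", function(object) {
  msg <- character()
  if (nrow(object@values) != nPixels(object@grid))
    msg <- c(msg, "values must have one row per grid pixel")
  if (ncol(object@values) != length(object@years))
    msg <- c(msg, "values must have one column per year")
  if (length(msg)) msg else TRUE
})

#' Construct an annual grid series
#' @param grid a [GridDef-class].
#' @param years integer year labels.
#' @param values pixels x years matrix.
#' @param units units tag.
#' @return An [AnnualGridSeries-class].
#' @export
annualGridSeries <- function(grid, years, values, units = "1") {
  new("AnnualGridSeries", grid = grid, years = as.integer(years),
      values = values, units = units)
}

#' Values of a gridded container
#'
#' Returns the numeric payload of the container: the pixels x epochs matrix
#' of an [EpochSeries-class], the pixels x years matrix of an
#' [AnnualGridSeries-class], or the pixels x 24 matrix of a
#' [Climatology-class].
#' @param x the container.
#' @return numeric matrix.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
setMethod("gridValues", "EpochSeries", function(x) x@values)
setMethod("gridValues", "AnnualGridSeries", function(x) x@values)
setMethod("gridValues", "Climatology", function(x) x@values)

#' Grid of a container
#' @param x a gridded object.
#' @return its [GridDef-class].
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
setMethod("gridOf", "RasterStack", function(x) x@grid)
setMethod("gridOf", "EpochSeries", function(x) x@grid)
setMethod("gridOf", "AnnualGridSeries", function(x) x@grid)
setMethod("gridOf", "Climatology", function(x) x@grid)

#' Units tag of a container
#' @param x a gridded object.
#' @return character units tag.
#' @export
setGeneric("unitsOf", function(x) standardGeneric("unitsOf"))
setMethod("unitsOf", "RasterStack", function(x) x@units)
setMethod("unitsOf", "EpochSeries", function(x) x@units)
setMethod("unitsOf", "AnnualGridSeries", function(x) x@units)
setMethod("unitsOf", "Climatology", function(x) x@units)

#' Calendar of an epoch series
#' @param x an [EpochSeries-class].
#' @return calendar data frame.
#' @export
calendarOf <- function(x) x@calendar

setMethod("show", "EpochSeries", function(object) {
  cal <- object@calendar
  cat(sprintf("%s: %d pixels x %d epochs [%s], %d-%d\n", class(object),
              nrow(object@values), ncol(object@values), object@units,
              min(cal$year), max(cal$year)))
})

setMethod("show", "Climatology", function(object) {
  cat(sprintf("Climatology [%s]: %d pixels x 24 epochs-of-year, years %s\n",
              object@units, nrow(object@values),
              paste(range(object@years), collapse = "-")))
})

setMethod("show", "AnnualGridSeries", function(object) {
  cat(sprintf("AnnualGridSeries [%s]: %d pixels x %d years (%s)\n",
              object@units, nrow(object@values), length(object@years),
              paste(range(object@years), collapse = "-")))
})

## ---------------------------------------------------------------------------
## PWS and downstream containers
## ---------------------------------------------------------------------------

#' Configuration of the lagged-anomaly regression
#'
#' @slot maxLagDays maximum lag in days (default 150).
#' @slot stepDays lag step in days, equal to the epoch cadence (default 15);
#'   lags are `0, 15, ..., maxLagDays`, i.e. 11 terms at the defaults.
#' @slot seasonMonths months whose epochs enter the response (default
#'   June-November, `6:11`).
#' @slot years years of the regression record (default 2016-2020).
#' @slot minValidFraction minimum valid fraction of the seasonal LFMC record
#'   for a pixel to be fit (default 0.5); pixels with a larger missing share
#'   are masked.
#' @slot pMin minimum number of regression rows (default 30).
#' @exportClass LagConfig
setClass("LagConfig",
  slots = c(maxLagDays = "numeric", stepDays = "numeric", seasonMonths = "integer",
            years = "integer", minValidFraction = "numeric", pMin = "integer"))

setValidity("LagConfig", function(object) {
  msg <- character()
  if (object@maxLagDays %% object@stepDays != 0)
    msg <- c(msg, "maxLagDays must be divisible by stepDays")
  if (!all(object@seasonMonths %in% 1:12)) msg <- c(msg, "seasonMonths must be in 1..12")
  if (object@minValidFraction < 0 || object@minValidFraction > 1)
    msg <- c(msg, "minValidFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a lag configuration
#' @param maxLagDays,stepDays,seasonMonths,years,minValidFraction,pMin see
#'   [LagConfig-class].
#' @return A [LagConfig-class].
#' @export
lagConfig <- function(maxLagDays = 150, stepDays = 15, seasonMonths = 6:11,
                      years = 2016:2020, minValidFraction = 0.5, pMin = 30) {
  new("LagConfig", maxLagDays = maxLagDays, stepDays = stepDays,
      seasonMonths = as.integer(seasonMonths), years = as.integer(years),
      minValidFraction = minValidFraction, pMin = as.integer(pMin))
}

#' Number of lag terms of a configuration
#' @param cfg a [LagConfig-class].
#' @return integer count (11 at the defaults).
#' @export
nLags <- function(cfg) as.integer(cfg@maxLagDays / cfg@stepDays) + 1L

#' One pixel's constrained lag-regression fit
#'
#' @slot beta non-negative lag coefficients (lag 0 first).
#' @slot gamma unconstrained intercept.
#' @slot r2 coefficient of determination against the response mean, clipped
#'   at 0 (see `flags`).
#' @slot nObs rows used in the fit.
#' @slot zeroFraction share of coefficients exactly zero.
#' @slot flags character flags ("rank_deficient", "negative_r2", ...).
#' @exportClass LagFit
setClass("LagFit",
  slots = c(beta = "numeric", gamma = "numeric", r2 = "numeric",
            nObs = "integer", zeroFraction = "numeric", flags = "character"))

setValidity("LagFit", function(object) {
  msg <- character()
  if (any(object@beta < 0)) msg <- c(msg, "all beta must be >= 0")
  if (length(object@r2) == 1L && !is.na(object@r2) &&
      (object@r2 < 0 || object@r2 > 1)) msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LagFit", function(object) {
  cat(sprintf("LagFit: PWS = %.4f over %d lags, gamma = %.4f, R2 = %.3f, n = %d\n",
              sum(object@beta), length(object@beta), object@gamma,
              object@r2, object@nObs))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Per-pixel plant-water-sensitivity map
#'
#' @slot grid the [GridDef-class].
#' @slot pws per-pixel PWS (sum of non-negative lag coefficients); `NA` where
#'   masked.
#' @slot r2 per-pixel regression R2.
#' @slot nObs per-pixel rows used.
#' @slot zeroFraction per-pixel share of zero coefficients.
#' @slot valid logical mask of pixels with a fit.
#' @exportClass PWSMap
setClass("PWSMap",
  slots = c(grid = "GridDef", pws = "numeric", r2 = "numeric",
            nObs = "integer", zeroFraction = "numeric", valid = "logical"))

setValidity("PWSMap", function(object) {
  msg <- character()
  n <- nPixels(object@grid)
  if (length(object@pws) != n || length(object@valid) != n)
    msg <- c(msg, "pws and valid must have one entry per pixel")
  if (any(object@pws[object@valid] < 0, na.rm = TRUE))
    msg <- c(msg, "PWS must be non-negative where valid")
  if (length(msg)) msg else TRUE
})

setMethod("gridOf", "PWSMap", function(x) x@grid)

#' PWS values of a map
#' @param x a [PWSMap-class].
#' @return per-pixel numeric vector (`NA` where masked).
#' @export
pwsValues <- function(x) x@pws

#' Valid-pixel mask of a PWS map
#' @param x a [PWSMap-class].
#' @return logical vector.
#' @export
validMask <- function(x) x@valid

#' Per-pixel fit R2 of a PWS map
#' @param x a [PWSMap-class].
#' @return numeric vector.
#' @export
fitR2 <- function(x) x@r2

setMethod("show", "PWSMap", function(object) {
  v <- object@pws[object@valid]
  cat(sprintf("PWSMap: %d / %d valid pixels; PWS median %.3f [%.3f, %.3f]; median fit R2 %.3f\n",
              sum(object@valid), nPixels(object@grid),
              if (length(v)) median(v) else NA, if (length(v)) min(v) else NA,
              if (length(v)) max(v) else NA,
              median(object@r2[object@valid], na.rm = TRUE)))
})

#' Equal-vegetated-area bin assignment of a PWS map
#'
#' @slot k number of bins.
#' @slot bin per-pixel bin index (`NA` outside the binned set), monotone in
#'   PWS.
#' @slot area vegetated area (km2) of each bin.
#' @slot repPws representative (area-weighted mean or median) PWS per bin.
#' @exportClass BinAssignment
setClass("BinAssignment",
  slots = c(k = "integer", bin = "integer", area = "numeric", repPws = "numeric"))

setValidity("BinAssignment", function(object) {
  msg <- character()
  if (length(object@area) != object@k || length(object@repPws) != object@k)
    msg <- c(msg, "area and repPws must have one entry per bin")
  if (any(!is.na(object@bin) & (object@bin < 1L | object@bin > object@k)))
    msg <- c(msg, "bin indices must lie in 1..k")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BinAssignment", function(object) {
  cat(sprintf("BinAssignment: %d bins, areas %.4g-%.4g km2, representative PWS %.3f-%.3f\n",
              object@k, min(object@area), max(object@area),
              min(object@repPws), max(object@repPws)))
})

#' PWS-derived wildfire hazard classes
#'
#' Zones: 1 = low (PWS below the first threshold), 2 = medium, 3 = high
#' (PWS above the second threshold).
#'
#' @slot grid the [GridDef-class].
#' @slot zone per-pixel integer zone (`NA` where PWS is masked).
#' @slot thresholds the two PWS thresholds (defaults 1 and 1.5).
#' @exportClass HazardMap
setClass("HazardMap",
  slots = c(grid = "GridDef", zone = "integer", thresholds = "numeric"))

setMethod("gridOf", "HazardMap", function(x) x@grid)

#' Hazard-zone labels of a hazard map
#' @param x a [HazardMap-class].
#' @return factor with levels low/medium/high (`NA` where masked).
#' @export
hazardZones <- function(x) {
  factor(c("low", "medium", "high")[x@zone], levels = c("low", "medium", "high"))
}

setMethod("show", "HazardMap", function(object) {
  tab <- table(hazardZones(object))
  cat(sprintf("HazardMap (thresholds %.2f / %.2f): low %d, medium %d, high %d pixels\n",
              object@thresholds[1], object@thresholds[2], tab["low"], tab["medium"], tab["high"]))
})

#' Per-pixel linear trend map
#'
#' @slot grid the [GridDef-class].
#' @slot trend per-pixel OLS slope against year (units yr-1 of the input).
#' @slot relTrend trend divided by the long-term pixel mean (yr-1).
#' @slot meanValue long-term pixel mean.
#' @slot nYears per-pixel years used.
#' @exportClass TrendMap
setClass("TrendMap",
  slots = c(grid = "GridDef", trend = "numeric", relTrend = "numeric",
            meanValue = "numeric", nYears = "integer"))

setMethod("gridOf", "TrendMap", function(x) x@grid)

#' Trend values of a trend map
#' @param x a [TrendMap-class].
#' @param relative return the relative (per-mean) trend instead.
#' @return numeric vector per pixel.
#' @export
trendValues <- function(x, relative = FALSE) if (relative) x@relTrend else x@trend

setMethod("show", "TrendMap", function(object) {
  ok <- !is.na(object@trend)
  cat(sprintf("TrendMap: %d valid pixels, mean trend %.4g, %0.1f%% positive\n",
              sum(ok), mean(object@trend[ok]), 100 * mean(object@trend[ok] > 0)))
})

## ---------------------------------------------------------------------------
## Synthetic truth
## ---------------------------------------------------------------------------

#' Ground truth of the synthetic generators
#'
#' Records everything needed to verify parameter recovery: the per-pixel
#' non-negative lag kernels (whose sums are the true PWS), the affine
#' slope law d(BA)/d(VPD) = a + b * PWS at the reference aggregation scale,
#' the trait-effect coefficients, and the master seed.
#'
#' @slot grid the [GridDef-class].
#' @slot kernels pixels x nLags matrix of non-negative generating kernels.
#' @slot pws per-pixel true PWS (`rowSums(kernels)`).
#' @slot slopeLaw named numeric `c(a, b)`; km2 hPa-1 (a) and km2 hPa-1 per
#'   PWS unit (b) at the 15-bin aggregation scale.
#' @slot traitEffects named numeric vector of 14 trait-effect coefficients.
#' @slot seed master seed of the truth record.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(grid = "GridDef", kernels = "matrix", pws = "numeric",
            slopeLaw = "numeric", traitEffects = "numeric", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (any(object@kernels < 0)) msg <- c(msg, "kernels must be non-negative")
  if (nrow(object@kernels) != nPixels(object@grid))
    msg <- c(msg, "kernels must have one row per pixel")
  if (!all(c("a", "b") %in% names(object@slopeLaw)))
    msg <- c(msg, "slopeLaw must carry a and b")
  if (length(msg)) msg else TRUE
})

setMethod("gridOf", "SyntheticTruth", function(x) x@grid)

#' True PWS of a synthetic truth record
#' @param x a [SyntheticTruth-class].
#' @return numeric per-pixel vector.
#' @export
truePws <- function(x) x@pws

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d pixels, %d lags, PWS in [%.3f, %.3f], slope law a=%.1f b=%.1f, seed %d\n",
              nrow(object@kernels), ncol(object@kernels), min(object@pws), max(object@pws),
              object@slopeLaw["a"], object@slopeLaw["b"], object@seed))
})
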