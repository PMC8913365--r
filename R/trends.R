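## Per-pixel VPD trends (OLS against year), relative trends, and the
## double-hazard classification joining high PWS with fast VPD rise.

#' Per-pixel linear trend map of annual values
#'
#' Ordinary least-squares slope of the annual value against the year at
#' every pixel with at least `minYears` annual values; the relative trend
#' divides by the pixel's long-term mean where that mean is positive.
#'
#' @param annual an [AnnualGridSeries-class] of annual means (e.g. VPD in
#'   hPa), or a pixels x years matrix.
#' @param years year labels (taken from the series if omitted).
#' @param grid [GridDef-class] (taken from the series if omitted).
#' @param minYears minimum annual values per pixel (default 10).
#' @return A [TrendMap-class]: `trend` in input units per year, `relTrend`
#'   in yr-1, `meanValue`, `nYears`.
#' @export
vpdTrendMap <- function(annual, years = NULL, grid = NULL, minYears = 10) {
  if (is(annual, "AnnualGridSeries")) {
    vals <- annual@values; years <- annual@years; grid <- annual@grid
  } else {
    vals <- as.matrix(annual)
    if (is.null(years) || is.null(grid)) stop("years and grid are required for matrix input")
  }
  stopifnot(ncol(vals) == length(years))
  n <- nrow(vals)
  x <- as.numeric(years)
  trend <- rep(NA_real_, n); meanV <- rep(NA_real_, n); nY <- rep(NA_integer_, n)
  complete <- rowSums(is.na(vals)) == 0L
  if (any(complete)) {
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    sub <- vals[complete, , drop = FALSE]
    trend[complete] <- as.numeric(sub %*% xc) / sxx
    meanV[complete] <- rowMeans(sub)
    nY[complete] <- length(x)
  }
  partial <- which(!complete)
  for (s in partial) {
    ok <- !is.na(vals[s, ])
    if (sum(ok) < minYears) next
    xi <- x[ok]; yi <- vals[s, ok]
    trend[s] <- sum((xi - mean(xi)) * (yi - mean(yi))) / sum((xi - mean(xi))^2)
    meanV[s] <- mean(yi)
    nY[s] <- sum(ok)
  }
  if (any(complete) && length(x) < minYears) {
    trend[complete] <- NA_real_; meanV[complete] <- NA_real_; nY[complete] <- NA_integer_
  }
  rel <- ifelse(!is.na(meanV) & meanV > 0, trend / meanV, NA_real_)
  new("TrendMap", grid = grid, trend = trend, relTrend = rel,
      meanValue = meanV, nYears = nY)
}

#' Double-hazard mask: high PWS co-occurring with fast VPD rise
#'
#' Two criteria: `joint_median` flags pixels where both PWS and the VPD
#' trend exceed their respective medians (computed over jointly valid
#' pixels); `high_pws_above_avg` flags pixels with PWS at or above
#' `pwsHigh` and a trend above the spatial average (mean by default,
#' median via `avg`).
#'
#' @param pws a [PWSMap-class].
#' @param trend a [TrendMap-class] on the same grid.
#' @param criterion `"joint_median"` or `"high_pws_above_avg"`.
#' @param pwsHigh high-PWS threshold for the second criterion (default
#'   1.5).
#' @param avg `"mean"` or `"median"` for "faster than average".
#' @param relative use the relative instead of the absolute trend.
#' @return list with `mask` (logical per pixel, `NA` outside the jointly
#'   valid set), `fraction` (flagged area / jointly valid area) and
#'   `thresholds`.
#' @export
doubleHazard <- function(pws, trend, criterion = c("joint_median", "high_pws_above_avg"),
                         pwsHigh = 1.5, avg = c("mean", "median"), relative = FALSE) {
  criterion <- match.arg(criterion)
  avg <- match.arg(avg)
  stopifnot(sameGrid(gridOf(pws), gridOf(trend)))
  p <- pwsValues(pws)
  tr <- trendValues(trend, relative = relative)
  joint <- validMask(pws) & !is.na(p) & !is.na(tr)
  if (!any(joint)) stop("no jointly valid pixels for the double-hazard mask")
  mask <- rep(NA, length(p))
  if (criterion == "joint_median") {
    thrP <- median(p[joint]); thrT <- median(tr[joint])
    mask[joint] <- p[joint] > thrP & tr[joint] > thrT
  } else {
    thrP <- pwsHigh
    thrT <- if (avg == "mean") mean(tr[joint]) else median(tr[joint])
    mask[joint] <- p[joint] >= thrP & tr[joint] > thrT
  }
  list(mask = mask, fraction = mean(mask[joint]),
       thresholds = c(pws = thrP, trend = thrT))
}
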