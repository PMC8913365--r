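## Half-monthly epoch calendar, seasonal climatologies and anomalies.
## Epochs run day 1-15 and day 16-end of each month, 24 per year, so the
## epoch-of-year index plays the role of "day of year" for a half-monthly
## product and one lag step equals one epoch (~15 d).

#' Build the half-monthly epoch calendar
#'
#' Each month contributes two epochs: days 1-15 and days 16 to month end
#' (24 per year). Epochs are non-overlapping and strictly increasing.
#'
#' @param years integer vector of calendar years to cover.
#' @return data frame with columns `year`, `month`, `eoy` (epoch of year,
#'   1..24), `start`, `end` (Dates) and `days`.
#' @examples
#' cal <- epochCalendar(2016:2017)
#' nrow(cal)  # 48
#' @export
epochCalendar <- function(years) {
  years <- sort(unique(as.integer(years)))
  rows <- lapply(years, function(y) {
    do.call(rbind, lapply(1:12, function(m) {
      first <- as.Date(sprintf("%d-%02d-01", y, m))
      nxt <- if (m == 12) as.Date(sprintf("%d-01-01", y + 1)) else
        as.Date(sprintf("%d-%02d-01", y, m + 1))
      monthEnd <- nxt - 1
      data.frame(year = y, month = m, eoy = c(2L * m - 1L, 2L * m),
                 start = c(first, first + 15),
                 end = c(first + 14, monthEnd))
    }))
  })
  cal <- do.call(rbind, rows)
  cal$days <- as.integer(cal$end - cal$start) + 1L
  rownames(cal) <- NULL
  cal
}

#' Composite daily values to half-monthly epochs
#'
#' Each epoch value is the arithmetic mean of its valid days; epochs with no
#' valid day are `NA`.
#'
#' @param daily numeric matrix, pixels x days (or a vector for one pixel).
#' @param dates `Date` vector, one per column of `daily`.
#' @param cal calendar from [epochCalendar()]; must be covered by `dates`.
#' @param grid the [GridDef-class] of the pixels.
#' @param units units tag for the result.
#' @return An [EpochSeries-class].
#' @export
epochComposite <- function(daily, dates, cal, grid, units = "1") {
  if (is.vector(daily)) daily <- matrix(daily, nrow = 1)
  stopifnot(ncol(daily) == length(dates))
  if (min(dates) > min(cal$start) || max(dates) < max(cal$end))
    stop(sprintf("daily series (%s to %s) does not cover the calendar span (%s to %s)",
                 min(dates), max(dates), min(cal$start), max(cal$end)))
  vals <- matrix(NA_real_, nrow(daily), nrow(cal))
  for (e in seq_len(nrow(cal))) {
    cols <- which(dates >= cal$start[e] & dates <= cal$end[e])
    if (!length(cols)) next
    sub <- daily[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    vals[, e] <- ifelse(n > 0, s / n, NA_real_)
  }
  epochSeries(grid, vals, cal, units = units)
}

#' Per-pixel seasonal climatology
#'
#' Means per pixel and epoch-of-year over the requested years; entries with
#' fewer than `minYears` contributing years are `NA`. Subtracting this
#' climatology removes the pixel-specific seasonal cycle so that anomalies
#' are comparable across locations with different seasonality.
#'
#' @param series an [EpochSeries-class].
#' @param years years to average over (default: all years in the calendar).
#' @param minYears minimum contributing years per entry (default 2; a
#'   single-year "climatology" would force that year's anomalies to zero).
#' @return A [Climatology-class].
#' @export
seasonalClimatology <- function(series, years = NULL, minYears = 2) {
  cal <- series@calendar
  if (is.null(years)) years <- unique(cal$year)
  years <- as.integer(years)
  if (!length(years)) stop("empty year set for climatology")
  vals <- matrix(NA_real_, nrow(series@values), 24L)
  cnts <- matrix(0L, nrow(series@values), 24L)
  for (e in 1:24) {
    cols <- which(cal$eoy == e & cal$year %in% years)
    if (!length(cols)) next
    sub <- series@values[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    m <- ifelse(n >= minYears, s / n, NA_real_)
    vals[, e] <- m
    cnts[, e] <- n
  }
  new("Climatology", grid = series@grid, values = vals, counts = cnts,
      years = years, units = series@units)
}

#' Anomalies relative to a seasonal climatology
#'
#' Value minus the matching pixel/epoch-of-year climatology entry; `NA`
#' wherever either side is missing.
#'
#' @param series an [EpochSeries-class].
#' @param clim a [Climatology-class] on the same grid.
#' @return An [AnomalySeries-class].
#' @export
anomaly <- function(series, clim) {
  stopifnot(sameGrid(series@grid, clim@grid))
  vals <- series@values - clim@values[, series@calendar$eoy, drop = FALSE]
  new("AnomalySeries", grid = series@grid, values = vals,
      calendar = series@calendar, units = series@units)
}

#' Fire-year label of a calendar month
#'
#' Fire years run April-March and are labelled by their starting calendar
#' year: March 2002 belongs to fire year 2001.
#'
#' @param year,month calendar year and month vectors.
#' @param yearStartMonth first month of the fire year (default 4, April).
#' @return integer fire-year labels.
#' @export
fireYearLabel <- function(year, month, yearStartMonth = 4) {
  ifelse(month >= yearStartMonth, year, year - 1L)
}

#' Aggregate an epoch series to fire years
#'
#' Burned area is summed and climate variables averaged over each complete
#' April-March fire year; fire years without full epoch coverage are
#' dropped.
#'
#' @param series an [EpochSeries-class].
#' @param yearStartMonth first month of the fire year (default 4).
#' @param stat `"sum"` (burned area) or `"mean"` (VPD and other intensive
#'   quantities).
#' @return An [AnnualGridSeries-class]; years label the fire year's starting
#'   calendar year. Warns and returns zero years if no fire year is fully
#'   covered.
#' @export
fireYearAggregate <- function(series, yearStartMonth = 4, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  cal <- series@calendar
  fy <- fireYearLabel(cal$year, cal$month, yearStartMonth)
  epochsPerYear <- 24L
  keep <- names(which(table(fy) == epochsPerYear))
  keep <- sort(as.integer(keep))
  if (!length(keep)) {
    warning("no complete fire year in the series")
    return(annualGridSeries(series@grid, integer(0),
                            matrix(NA_real_, nrow(series@values), 0), series@units))
  }
  out <- matrix(NA_real_, nrow(series@values), length(keep))
  for (i in seq_along(keep)) {
    cols <- which(fy == keep[i])
    sub <- series@values[, cols, drop = FALSE]
    out[, i] <- if (stat == "sum") rowSums(sub) else rowMeans(sub)
  }
  annualGridSeries(series@grid, keep, out, series@units)
}

#' Aggregate monthly values to fire years
#'
#' Matrix-level variant of [fireYearAggregate()] for monthly inputs.
#'
#' @param values pixels x months matrix (or vector for one pixel).
#' @param year,month calendar year/month per column.
#' @param yearStartMonth first month of the fire year (default 4).
#' @param stat `"sum"` or `"mean"`.
#' @return list with `years` (complete fire years) and `values`
#'   (pixels x years matrix).
#' @export
monthlyFireYearAggregate <- function(values, year, month, yearStartMonth = 4,
                                     stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  fy <- fireYearLabel(year, month, yearStartMonth)
  keep <- sort(as.integer(names(which(table(fy) == 12L))))
  if (!length(keep)) warning("no complete fire year in the series")
  out <- matrix(NA_real_, nrow(values), length(keep))
  for (i in seq_along(keep)) {
    sub <- values[, fy == keep[i], drop = FALSE]
    out[, i] <- if (stat == "sum") rowSums(sub) else rowMeans(sub)
  }
  list(years = keep, values = out)
}
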