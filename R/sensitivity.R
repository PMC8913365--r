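## Link PWS to the sensitivity of burned area to VPD: sort vegetated pixels
## by PWS into k bins of equal vegetated area, pool each bin's annual burned
## area (sum) and VPD (area-weighted mean), regress burned area on VPD per
## bin, then regress the per-bin slopes on representative PWS.

#' Equal-vegetated-area PWS bins
#'
#' Valid vegetated pixels are sorted by PWS (ties broken by pixel index) and
#' the cumulative vegetated area is split into `k` near-equal parts, so the
#' largest and smallest bin differ by at most one pixel's area.
#'
#' @param pws a [PWSMap-class].
#' @param vegMask logical per-pixel vegetated mask (default: all valid
#'   pixels).
#' @param pixArea per-pixel area vector (default: the grid's uniform pixel
#'   area).
#' @param k bin count (default 15; 10 is the usual robustness variant).
#' @param representative `"area_mean"` (default) or `"median"` per-bin PWS
#'   summary.
#' @return A [BinAssignment-class].
#' @export
equalAreaBins <- function(pws, vegMask = NULL, pixArea = NULL, k = 15,
                          representative = c("area_mean", "median")) {
  representative <- match.arg(representative)
  v <- pwsValues(pws)
  n <- length(v)
  if (is.null(vegMask)) vegMask <- rep(TRUE, n)
  if (is.null(pixArea)) pixArea <- rep(pixelArea(gridOf(pws)), n)
  use <- which(validMask(pws) & vegMask & !is.na(v))
  if (k < 1) stop("k must be >= 1")
  if (length(use) < k)
    stop(sprintf("k = %d exceeds the %d valid vegetated pixels", k, length(use)))
  ord <- use[order(v[use], use)]
  cum <- cumsum(pixArea[ord])
  total <- cum[length(cum)]
  binOrd <- pmin(k, pmax(1L, ceiling(cum * k / total - 1e-9)))
  bin <- rep(NA_integer_, n)
  bin[ord] <- as.integer(binOrd)
  area <- as.numeric(tapply(pixArea[ord], binOrd, sum))
  repPws <- vapply(seq_len(k), function(j) {
    members <- ord[binOrd == j]
    if (representative == "area_mean")
      sum(v[members] * pixArea[members]) / sum(pixArea[members])
    else median(v[members])
  }, numeric(1))
  new("BinAssignment", k = as.integer(k), bin = bin, area = area, repPws = repPws)
}

#' Pool per-pixel annual series into bins
#'
#' Per bin and fire year: burned area is the sum over member pixels, VPD the
#' vegetated-area-weighted mean (`vpdWeighted = FALSE` switches to the
#' unweighted pixel mean).
#'
#' @param burned per-pixel [AnnualGridSeries-class] of burned area (km2).
#' @param vpd per-pixel [AnnualGridSeries-class] of fire-year VPD (hPa).
#' @param bins a [BinAssignment-class].
#' @param pixArea per-pixel areas (default: uniform grid pixel area).
#' @param vpdWeighted area-weight the bin VPD (default TRUE).
#' @return list with `years`, `ba` (k x years matrix, km2) and `vpd`
#'   (k x years matrix, hPa).
#' @export
binAnnualSeries <- function(burned, vpd, bins, pixArea = NULL, vpdWeighted = TRUE) {
  stopifnot(identical(burned@years, vpd@years))
  n <- nrow(burned@values)
  if (is.null(pixArea)) pixArea <- rep(pixelArea(gridOf(burned)), n)
  k <- bins@k
  baM <- matrix(NA_real_, k, length(burned@years))
  vpdM <- matrix(NA_real_, k, length(burned@years))
  for (j in seq_len(k)) {
    members <- which(!is.na(bins@bin) & bins@bin == j)
    if (!length(members)) stop(sprintf("bin %d is empty", j))
    baM[j, ] <- colSums(burned@values[members, , drop = FALSE])
    w <- if (vpdWeighted) pixArea[members] else rep(1, length(members))
    vpdM[j, ] <- colSums(vpd@values[members, , drop = FALSE] * w) / sum(w)
  }
  list(years = burned@years, ba = baM, vpd = vpdM)
}

#' Ordinary least-squares slope with classical inference
#'
#' @param y,x paired annual values (>= 3 pairs; `x` must vary).
#' @return list with `slope`, `intercept`, `stderr` (classical standard
#'   error of the slope), `r2`, `p` (two-sided) and `n`.
#' @examples
#' olsSlope(c(2, 1, 4, 3), 1:4)$slope  # 0.6
#' @export
olsSlope <- function(y, x) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 paired values for a slope")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("x is constant; slope undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  ssRes <- sum(res^2); ssTot <- sum((y - mean(y))^2)
  sigma2 <- ssRes / (n - 2)
  stderr <- sqrt(sigma2 / sxx)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  tval <- if (stderr > 0) slope / stderr else Inf * sign(slope)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = slope, intercept = intercept, stderr = stderr, r2 = r2, p = p, n = n)
}

#' Per-bin burned-area-vs-VPD slopes
#'
#' @param binSeries output of [binAnnualSeries()].
#' @return data frame with one row per bin: `bin`, `slope` (km2 hPa-1),
#'   `stderr`, `r2`, `p`, `n`.
#' @export
binSlopes <- function(binSeries) {
  k <- nrow(binSeries$ba)
  rows <- lapply(seq_len(k), function(j) {
    s <- olsSlope(binSeries$ba[j, ], binSeries$vpd[j, ])
    data.frame(bin = j, slope = s$slope, stderr = s$stderr, r2 = s$r2,
               p = s$p, n = s$n)
  })
  do.call(rbind, rows)
}

#' Final regression of per-bin slope on PWS
#'
#' Unweighted OLS of the per-bin d(burned area)/d(VPD) slopes on the bins'
#' representative PWS. The displayed per-bin standard errors do not enter
#' the fit.
#'
#' @param bins a [BinAssignment-class].
#' @param slopes data frame from [binSlopes()] (or any data frame with a
#'   `slope` column ordered by bin).
#' @return list with `coefficient` (km2 hPa-1 per PWS unit), `intercept`,
#'   `stderr`, `r2`, `p` and `n`.
#' @export
sensitivityCurve <- function(bins, slopes) {
  if (bins@k < 3) stop("need at least 3 bins for the slope-vs-PWS regression")
  s <- olsSlope(slopes$slope, bins@repPws)
  list(coefficient = s$slope, intercept = s$intercept, stderr = s$stderr,
       r2 = s$r2, p = s$p, n = s$n)
}

#' Classify PWS into hazard zones
#'
#' Low hazard below the first threshold, high above the second, medium for
#' the closed interval between them (the only exhaustive, non-overlapping
#' reading of the three classes).
#'
#' @param pws a [PWSMap-class] or numeric PWS vector.
#' @param thresholds the two class boundaries (default `c(1, 1.5)`).
#' @param grid required [GridDef-class] when `pws` is a plain vector.
#' @return A [HazardMap-class]; masked pixels stay `NA`.
#' @export
classifyHazard <- function(pws, thresholds = c(1, 1.5), grid = NULL) {
  if (is(pws, "PWSMap")) {
    v <- pwsValues(pws); grid <- gridOf(pws)
  } else {
    v <- as.numeric(pws)
    if (is.null(grid)) stop("grid must be supplied for a plain PWS vector")
  }
  zone <- rep(NA_integer_, length(v))
  zone[!is.na(v) & v < thresholds[1]] <- 1L
  zone[!is.na(v) & v >= thresholds[1] & v <= thresholds[2]] <- 2L
  zone[!is.na(v) & v > thresholds[2]] <- 3L
  new("HazardMap", grid = grid, zone = zone, thresholds = thresholds)
}

#' Percent-change sensitivity of burned area to VPD
#'
#' Transforms each bin's burned-area series to percent change relative to
#' the baseline year, then regresses it on the bin's annual VPD; the slope
#' is in % per hPa and is invariant to rescaling all burned areas.
#'
#' @param binSeries output of [binAnnualSeries()].
#' @param baselineYear baseline fire year (default: the first year present).
#' @return data frame with one row per bin: `bin`, `slope` (% hPa-1),
#'   `stderr`, `r2`, `p`, `n`.
#' @export
percentChangeSensitivity <- function(binSeries, baselineYear = NULL) {
  if (is.null(baselineYear)) baselineYear <- binSeries$years[1]
  i0 <- match(baselineYear, binSeries$years)
  if (is.na(i0)) stop(sprintf("baseline year %d not present", baselineYear))
  base <- binSeries$ba[, i0]
  if (any(base <= 0)) stop("baseline burned area must be positive in every bin")
  pct <- 100 * sweep(sweep(binSeries$ba, 1, base), 1, base, "/")
  rows <- lapply(seq_len(nrow(pct)), function(j) {
    s <- olsSlope(pct[j, ], binSeries$vpd[j, ])
    data.frame(bin = j, slope = s$slope, stderr = s$stderr, r2 = s$r2,
               p = s$p, n = s$n)
  })
  do.call(rbind, rows)
}
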