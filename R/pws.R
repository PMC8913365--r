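## Plant-water sensitivity: per pixel, regress the live fuel moisture
## anomaly on dead fuel moisture anomalies lagged 0-150 d (11 half-monthly
## steps), with non-negative slopes and a free intercept. PWS is the
## unweighted sum of the slopes, so concurrent and antecedent conditions
## count equally; the non-negativity constraint forbids the unphysical case
## of a wetter climate drying live fuels.

#' Build the lagged-anomaly design for one pixel
#'
#' One row per seasonal (June-November by default) epoch `t` in the
#' configured years for which the response anomaly and all lagged predictor
#' anomalies are present (listwise deletion). Column `i` holds the
#' predictor anomaly `i - 1` epoch steps (15 d each) behind `t`; column 1 is
#' the concurrent value.
#'
#' @param lfmcAnom response [AnomalySeries-class] (live fuel moisture).
#' @param dfmcAnom predictor [AnomalySeries-class] (dead fuel moisture, or
#'   VPD for the modified sensitivity variant).
#' @param cfg a [LagConfig-class].
#' @param pixel pixel index.
#' @return list with `y` (response vector), `X` (rows x 11 design matrix)
#'   and `epochs` (calendar row indices of the rows). Zero rows is a valid
#'   result (the pixel is flagged invalid downstream, not an error).
#' @export
buildLagDesign <- function(lfmcAnom, dfmcAnom, cfg, pixel) {
  calY <- lfmcAnom@calendar; calX <- dfmcAnom@calendar
  if (!identical(calY[c("year", "eoy")], calX[c("year", "eoy")]))
    stop("response and predictor anomalies must share one epoch calendar")
  nl <- nLags(cfg)
  tIdx <- which(calY$year %in% cfg@years & calY$month %in% cfg@seasonMonths)
  tIdx <- tIdx[tIdx >= nl]  # need the full lag history
  yv <- lfmcAnom@values[pixel, tIdx]
  X <- vapply(seq_len(nl), function(i) dfmcAnom@values[pixel, tIdx - (i - 1L)],
              numeric(length(tIdx)))
  if (length(tIdx) == 1L) X <- matrix(X, nrow = 1L)
  ok <- !is.na(yv) & rowSums(is.na(X)) == 0L
  list(y = yv[ok], X = X[ok, , drop = FALSE], epochs = tIdx[ok])
}

#' Fit the non-negative distributed-lag regression
#'
#' Minimises `sum((y - X beta - gamma)^2)` subject to `beta >= 0` with
#' `gamma` unconstrained. The intercept is handled exactly by centring `y`
#' and the columns of `X` before the non-negative solve, then
#' `gamma = mean(y) - colMeans(X) . beta`.
#'
#' @param y response vector.
#' @param X design matrix (11 lag columns).
#' @param tol solver tolerance passed to [nnlsFit()].
#' @return A [LagFit-class]. R2 is computed against the mean of `y` and
#'   clipped at 0 (flag `"negative_r2"` records clipping; with a free
#'   intercept the unclipped value cannot drop below 0). A constant `y`
#'   yields R2 `NA` with flag `"constant_response"`.
#' @export
fitNonnegLagRegression <- function(y, X, tol = 1e-10) {
  stopifnot(length(y) == nrow(X))
  ybar <- mean(y); xbar <- colMeans(X)
  fit <- nnlsFit(sweep(X, 2, xbar), y - ybar, tol = tol)
  beta <- fit$beta
  gamma <- ybar - sum(xbar * beta)
  ssTot <- sum((y - ybar)^2)
  ssRes <- sum((y - X %*% beta - gamma)^2)
  flags <- character()
  if (fit$rankDeficient) flags <- c(flags, "rank_deficient")
  if (ssTot <= 0) {
    r2 <- NA_real_
    flags <- c(flags, "constant_response")
  } else {
    r2 <- 1 - ssRes / ssTot
    if (r2 < 0) { r2 <- 0; flags <- c(flags, "negative_r2") }
  }
  new("LagFit", beta = beta, gamma = gamma, r2 = r2, nObs = length(y),
      zeroFraction = mean(beta == 0), flags = flags)
}

#' PWS of a lag fit
#'
#' The unweighted sum of the non-negative lag coefficients; the intercept
#' is excluded.
#'
#' @param fit a [LagFit-class].
#' @return non-negative scalar.
#' @export
pwsFromFit <- function(fit) sum(fit@beta)

#' Estimate the PWS map
#'
#' Runs the full per-pixel chain: epoch-of-year climatologies over the
#' configured years (all epochs of those years, so that lagged predictors
#' reaching back before the season are defined), anomalies, lagged design,
#' constrained fit, and PWS. A pixel is masked when more than
#' `1 - minValidFraction` of its seasonal response record is missing, or
#' when fewer than `pMin` design rows survive listwise deletion.
#'
#' @param lfmc response [EpochSeries-class] (live fuel moisture, %).
#' @param predictor predictor [EpochSeries-class]; dead fuel moisture for
#'   standard PWS, VPD for the modified variant used as a circularity
#'   check.
#' @param cfg a [LagConfig-class].
#' @param minYears minimum contributing years per climatology entry.
#' @return A [PWSMap-class]. Warns if no pixel could be fit.
#' @examples
#' \donttest{
#' truth <- syntheticTruth(gridDef(8, 8), seed = 1)
#' clim <- simulateClimate(gridDef(8, 8), years = 2015:2020, seed = 1)
#' lfmc <- simulateLfmc(clim$dfmc, truth, noiseSd = 0, seed = 1)
#' pws <- estimatePwsMap(lfmc, clim$dfmc, lagConfig())
#' cor(pwsValues(pws), truePws(truth))
#' }
#' @export
estimatePwsMap <- function(lfmc, predictor, cfg = lagConfig(), minYears = 2) {
  stopifnot(sameGrid(lfmc@grid, predictor@grid))
  cal <- lfmc@calendar
  lfmcAnom <- anomaly(lfmc, seasonalClimatology(lfmc, cfg@years, minYears))
  predAnom <- anomaly(predictor, seasonalClimatology(predictor, cfg@years, minYears))
  seasonCols <- which(cal$year %in% cfg@years & cal$month %in% cfg@seasonMonths)
  recordLen <- length(seasonCols)
  n <- nPixels(lfmc@grid)
  pws <- rep(NA_real_, n); r2 <- rep(NA_real_, n)
  nObs <- rep(NA_integer_, n); zf <- rep(NA_real_, n)
  valid <- logical(n)
  nl <- nLags(cfg)
  for (s in seq_len(n)) {
    validFrac <- mean(!is.na(lfmc@values[s, seasonCols]))
    if (recordLen == 0L || (1 - validFrac) > (1 - cfg@minValidFraction) + 1e-12) next
    d <- buildLagDesign(lfmcAnom, predAnom, cfg, s)
    if (length(d$y) < cfg@pMin) next
    fit <- fitNonnegLagRegression(d$y, d$X)
    pws[s] <- pwsFromFit(fit)
    r2[s] <- fit@r2
    nObs[s] <- fit@nObs
    zf[s] <- fit@zeroFraction
    valid[s] <- TRUE
  }
  if (!any(valid)) warning("no valid pixels: PWS map is empty")
  new("PWSMap", grid = lfmc@grid, pws = pws, r2 = r2, nObs = nObs,
      zeroFraction = zf, valid = valid)
}
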