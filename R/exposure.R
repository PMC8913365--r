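## WUI population exposure by hazard zone, plus the confounder screens used
## to check that the PWS - burned-area link is not an artefact of climate or
## fuel-availability gradients.

#' WUI population exposure by hazard zone
#'
#' Sums the population of wildland-urban-interface pixels per hazard zone
#' for two census epochs, and reports percent change and each zone's share
#' of the total WUI population per epoch.
#'
#' @param wuiMask logical per-pixel WUI mask (matrix or vector).
#' @param pop1990,pop2010 per-pixel populations (matrix or vector; >= 0).
#' @param hazard a [HazardMap-class] defined on the WUI pixels.
#' @return data frame with rows `low`, `medium`, `high`, `total` and
#'   columns `pop1990`, `pop2010`, `pctChange` (one decimal; `NA` and
#'   `flag = "zero_base"` where the 1990 population is zero) and
#'   `share1990`, `share2010` (each summing to 1 over the zones).
#' @export
wuiExposure <- function(wuiMask, pop1990, pop2010, hazard) {
  w <- as.vector(if (is.matrix(wuiMask)) t(wuiMask) else wuiMask)
  p1 <- as.vector(if (is.matrix(pop1990)) t(pop1990) else pop1990)
  p2 <- as.vector(if (is.matrix(pop2010)) t(pop2010) else pop2010)
  if (any(p1 < 0, na.rm = TRUE) || any(p2 < 0, na.rm = TRUE))
    stop("populations must be non-negative")
  zone <- hazard@zone
  use <- which(w & !is.na(zone))
  s1 <- vapply(1:3, function(z) sum(p1[use][zone[use] == z], na.rm = TRUE), numeric(1))
  s2 <- vapply(1:3, function(z) sum(p2[use][zone[use] == z], na.rm = TRUE), numeric(1))
  t1 <- sum(s1); t2 <- sum(s2)
  pop1 <- c(s1, t1); pop2 <- c(s2, t2)
  pct <- ifelse(pop1 > 0, round(100 * (pop2 - pop1) / pop1, 1), NA_real_)
  out <- data.frame(zone = c("low", "medium", "high", "total"),
                    pop1990 = pop1, pop2010 = pop2, pctChange = pct,
                    share1990 = c(if (t1 > 0) s1 / t1 else rep(NA_real_, 3), 1),
                    share2010 = c(if (t2 > 0) s2 / t2 else rep(NA_real_, 3), 1),
                    flag = ifelse(pop1 > 0, "", "zero_base"))
  rownames(out) <- out$zone
  out
}

#' Screen PWS against potential biogeographical confounders
#'
#' Pearson correlation (and its square) between PWS and each supplied
#' covariate map over jointly valid pixels; typical covariates are mean and
#' variance of VPD, mean and dry-season NDVI, dry-season length and the
#' modified (VPD-predictor) PWS.
#'
#' @param pws a [PWSMap-class] or numeric per-pixel vector.
#' @param covariates named list of per-pixel numeric vectors (or matrices).
#' @param minN minimum jointly valid pixels per covariate (default 30).
#' @return data frame with one row per covariate: `covariate`, `r`, `r2`,
#'   `n`, `flag` (`"constant"` when the covariate does not vary,
#'   `"insufficient_n"` below `minN`).
#' @export
confounderScreen <- function(pws, covariates, minN = 30) {
  y <- if (is(pws, "PWSMap")) pwsValues(pws) else as.numeric(pws)
  rows <- lapply(names(covariates), function(nm) {
    xv <- covariates[[nm]]
    x <- as.vector(if (is.matrix(xv)) t(xv) else xv)
    ok <- !is.na(x) & !is.na(y)
    flag <- ""
    r <- NA_real_
    if (sum(ok) < minN) flag <- "insufficient_n"
    else if (sd(x[ok]) == 0 || sd(y[ok]) == 0) flag <- "constant"
    else r <- cor(x[ok], y[ok])
    data.frame(covariate = nm, r = r, r2 = r^2, n = sum(ok), flag = flag)
  })
  do.call(rbind, rows)
}

#' Sensitivity of fuel availability (NDVI) to antecedent precipitation
#'
#' Per pixel, the OLS slope of fire-season NDVI on antecedent (December-May)
#' precipitation totals; per land-cover class (and optionally per
#' mean-precipitation group), the Pearson correlation of that slope with
#' PWS. A positive correlation would indicate that the PWS - burned-area
#' link is confounded by precipitation-driven fuel growth.
#'
#' @param ndvi pixels x years matrix of fire-season NDVI.
#' @param precip pixels x years matrix of antecedent precipitation totals.
#' @param landcover per-pixel land-cover codes.
#' @param pws a [PWSMap-class] or numeric per-pixel vector.
#' @param precipGroups optional number of mean-precipitation quantile groups
#'   within each land cover.
#' @param minYears minimum paired years per pixel (default 5).
#' @return data frame with `landcover`, `group` (`NA` when ungrouped), `r`,
#'   `n`, `flag` (`"constant_slope"` when the per-pixel slopes do not vary).
#' @export
ndviPrecipSensitivity <- function(ndvi, precip, landcover, pws,
                                  precipGroups = NULL, minYears = 5) {
  stopifnot(all(dim(ndvi) == dim(precip)))
  y <- if (is(pws, "PWSMap")) pwsValues(pws) else as.numeric(pws)
  n <- nrow(ndvi)
  slope <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    ok <- !is.na(ndvi[s, ]) & !is.na(precip[s, ])
    if (sum(ok) < minYears) next
    xp <- precip[s, ok]
    if (sd(xp) == 0) next  # constant precipitation: slope undefined
    slope[s] <- sum((xp - mean(xp)) * (ndvi[s, ok] - mean(ndvi[s, ok]))) /
      sum((xp - mean(xp))^2)
  }
  meanP <- rowMeans(precip, na.rm = TRUE)
  corCell <- function(idx) {
    ok <- idx[!is.na(slope[idx]) & !is.na(y[idx])]
    if (length(ok) < 3) return(list(r = NA_real_, n = length(ok), flag = "insufficient_n"))
    tolS <- 1e-10 * (abs(mean(slope[ok])) + 1)
    if (sd(slope[ok]) < tolS) return(list(r = NA_real_, n = length(ok), flag = "constant_slope"))
    if (sd(y[ok]) == 0) return(list(r = NA_real_, n = length(ok), flag = "constant_pws"))
    list(r = cor(slope[ok], y[ok]), n = length(ok), flag = "")
  }
  rows <- list()
  for (lc in sort(unique(landcover[!is.na(landcover)]))) {
    idx <- which(landcover == lc)
    if (is.null(precipGroups)) {
      cc <- corCell(idx)
      rows[[length(rows) + 1]] <- data.frame(landcover = lc, group = NA_integer_,
                                             r = cc$r, n = cc$n, flag = cc$flag)
    } else {
      br <- quantile(meanP[idx], probs = seq(0, 1, length.out = precipGroups + 1),
                     na.rm = TRUE)
      grp <- cut(meanP[idx], breaks = unique(br), include.lowest = TRUE, labels = FALSE)
      for (g in sort(unique(grp[!is.na(grp)]))) {
        cc <- corCell(idx[!is.na(grp) & grp == g])
        rows[[length(rows) + 1]] <- data.frame(landcover = lc, group = g,
                                               r = cc$r, n = cc$n, flag = cc$flag)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pixelSlopes") <- slope
  out
}
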