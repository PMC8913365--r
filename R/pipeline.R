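## End-to-end orchestration: simulate -> preprocess/PWS -> sensitivity ->
## drivers -> trends/exposure, from a single configuration list, with a
## machine-readable report. Stages read from and write to a shared state,
## so a subset of stages can be re-run against intermediates from an
## earlier run.

#' Default pipeline configuration
#'
#' Every numeric default is the analysis default: lags 0-150 d in 15 d
#' steps over June-November, 15 equal-area bins, hazard thresholds 1 and
#' 1.5, 50 trees / node size 6 / 3 folds for the trait forest, April fire
#' years, 50% valid-record masking. The grid and simulated year span
#' default to the standard 64 x 64, 2015-2020 fixture.
#'
#' @param ... named overrides of any top-level entry.
#' @return configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    grid = list(nRow = 64, nCol = 64, pixelArea = 16),
    years = 2015:2020,
    lag = list(maxLagDays = 150, stepDays = 15, seasonMonths = 6:11,
               years = 2016:2020, minValidFraction = 0.5, pMin = 30),
    bins = 15,
    hazardThresholds = c(1, 1.5),
    fireYearStartMonth = 4,
    slopeLaw = c(a = 350, b = 175),
    targetR2 = 0.3,
    baNoiseSd = 1,
    traits = list(coarseFactor = 8, noiseSd = 0.3),
    forest = list(numTrees = 50, minNodeSize = 6, folds = 3),
    wui = list(totalPop1990 = 1e7,
               growthByZone = c(low = 2.07, medium = 1.95, high = 2.60),
               wuiFrac = 0.3, jitterSd = 0))
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: climate + truth simulation, LFMC generation, PWS
#' estimation, equal-area binning and the burned-area-vs-VPD sensitivity
#' curve, trait attribution, VPD trend and double-hazard maps, and WUI
#' exposure. Returns a report of all recovered coefficients next to their
#' generating values; if `outDir` is given, per-stage CSV outputs and a
#' JSON report are written there.
#'
#' @param config configuration list from [pipelineConfig()].
#' @param seed master seed; every stage derives its seed from it.
#' @param outDir optional output directory.
#' @param stages character subset of
#'   `c("simulate", "pws", "sensitivity", "drivers", "exposure")` to run;
#'   later stages need the `state` of an earlier run covering the earlier
#'   stages.
#' @param state state list from a previous invocation (for re-running a
#'   stage subset without recomputation).
#' @return list with `report` (named results) and `state` (all
#'   intermediates), invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(), seed = 42, outDir = NULL,
                        stages = c("simulate", "pws", "sensitivity",
                                   "drivers", "exposure"),
                        state = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  st <- if (is.null(state)) list() else state
  report <- if (is.null(st$report)) list(seed = seed) else st$report

  if ("simulate" %in% stages) {
    grid <- gridDef(config$grid$nRow, config$grid$nCol, pixelArea = config$grid$pixelArea)
    st$truth <- syntheticTruth(grid, seed = seed, a = config$slopeLaw["a"],
                               b = config$slopeLaw["b"])
    st$climate <- simulateClimate(grid, config$years, seed = seed)
    st$lfmc <- simulateLfmc(st$climate$dfmc, st$truth, targetR2 = config$targetR2,
                            seed = seed)
    report$truth_slope_law <- as.list(st$truth@slopeLaw)
  }
  if ("pws" %in% stages) {
    if (is.null(st$lfmc)) stop("stage 'pws' needs intermediates from 'simulate'")
    lagCfg <- do.call(lagConfig, config$lag)
    st$pws <- estimatePwsMap(st$lfmc, st$climate$dfmc, lagCfg)
    ok <- validMask(st$pws)
    report$pws_valid_pixels <- sum(ok)
    report$pws_median_fit_r2 <- median(fitR2(st$pws)[ok])
    report$pws_truth_correlation <- cor(pwsValues(st$pws)[ok], truePws(st$truth)[ok])
  }
  if ("sensitivity" %in% stages) {
    if (is.null(st$pws)) stop("stage 'sensitivity' needs intermediates from 'pws'")
    st$bins <- equalAreaBins(st$pws, k = config$bins)
    st$vpdAnnual <- fireYearAggregate(st$climate$vpd, config$fireYearStartMonth, "mean")
    st$ba <- simulateFire(st$truth, st$vpdAnnual, baNoiseSd = config$baNoiseSd,
                          seed = seed)
    st$binSeries <- binAnnualSeries(st$ba, st$vpdAnnual, st$bins)
    st$slopes <- binSlopes(st$binSeries)
    st$curve <- sensitivityCurve(st$bins, st$slopes)
    st$hazard <- classifyHazard(st$pws, thresholds = config$hazardThresholds)
    report$sensitivity_coefficient <- st$curve$coefficient
    report$sensitivity_r2 <- st$curve$r2
    report$slope_range <- range(st$slopes$slope)
  }
  if ("drivers" %in% stages) {
    if (is.null(st$pws)) stop("stage 'drivers' needs intermediates from 'pws'")
    st$traits <- simulateTraits(st$truth, coarseFactor = config$traits$coarseFactor,
                                noiseSd = config$traits$noiseSd, seed = seed)
    st$importance <- fitTraitImportance(st$traits, st$pws,
                                        numTrees = config$forest$numTrees,
                                        minNodeSize = config$forest$minNodeSize,
                                        folds = config$forest$folds, seed = seed)
    report$top_trait <- names(which.max(st$importance$importance))
    report$trait_cv_r2 <- mean(st$importance$cvR2)
  }
  if ("exposure" %in% stages) {
    if (is.null(st$hazard)) stop("stage 'exposure' needs intermediates from 'sensitivity'")
    annualVpd <- fireYearAggregate(st$climate$vpd, 1, "mean")
    st$trend <- vpdTrendMap(annualVpd, minYears = min(10, length(annualVpd@years)))
    st$double <- doubleHazard(st$pws, st$trend)
    st$wuiData <- do.call(simulateWui, c(list(hazard = st$hazard, seed = seed),
                                         config$wui))
    st$exposure <- wuiExposure(st$wuiData$wuiMask, st$wuiData$pop1990,
                               st$wuiData$pop2010, st$hazard)
    report$double_hazard_fraction <- st$double$fraction
    report$wui_total_pct_change <- st$exposure["total", "pctChange"]
  }
  st$report <- report

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(st$pws))
      writeGridCsv(pwsValues(st$pws), gridOf(st$pws),
                   file.path(outDir, "pws_map.csv"), units = "1")
    if (!is.null(st$slopes))
      writeTableCsv(cbind(st$slopes, repPws = st$bins@repPws),
                    file.path(outDir, "bin_slopes.csv"))
    if (!is.null(st$importance))
      writeTableCsv(data.frame(trait = names(st$importance$importance),
                               importance = st$importance$importance),
                    file.path(outDir, "trait_importance.csv"))
    if (!is.null(st$exposure))
      writeTableCsv(st$exposure, file.path(outDir, "wui_exposure.csv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(report = report, state = st))
}
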