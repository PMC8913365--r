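# pwsfire

Plant-water sensitivity (PWS) and wildfire vulnerability analysis for
gridded fuel-moisture, climate and burned-area data, with a synthetic-data
generator that makes the whole pipeline testable against a known ground
truth.

## The problem and the method

Rising vapour pressure deficit (VPD) has increased burned area across arid
ecosystems, but not uniformly: for the same rise in VPD, burned area grows
more where live vegetation moisture responds strongly to climatic water
limitation. `pwsfire` quantifies that response per pixel and propagates it
through a hazard and exposure analysis:

1. **PWS estimation.** Live fuel moisture content anomalies (LFMC′, %) are
   regressed on dead fuel moisture content anomalies (DFMC′, %) at lags
   i = 0, 15, …, 150 d (11 half-monthly steps):

   LFMC′<sub>s,t</sub> = Σ<sub>i</sub> β<sub>s,i</sub> · DFMC′<sub>s,t−i</sub> + γ<sub>s</sub>,  β<sub>s,i</sub> ≥ 0

   fitted by exact active-set non-negative least squares with a free
   intercept, on June–November epochs of a five-year record, and

   PWS<sub>s</sub> = Σ<sub>i</sub> β<sub>s,i</sub>.

   Anomalies are deviations from the pixel's epoch-of-year climatology;
   pixels with more than half the seasonal LFMC record missing are masked.
2. **Sensitivity of burned area to VPD.** The PWS map is split into k = 15
   bins of equal vegetated area; per bin, annual burned area (April–March
   fire years, km²) is regressed on annual mean VPD (hPa); the per-bin
   slopes d(BA)/d(VPD) are then regressed on the bins' representative PWS.
   Hazard classes: low (PWS < 1), medium (1–1.5), high (> 1.5).
3. **Trait attribution.** A 50-tree random-forest regression of PWS on 14
   plant and soil hydraulic trait maps (minimum node size 6, impurity
   importance normalised to sum 1, 3-fold cross-validated R²).
4. **Trends and exposure.** Per-pixel OLS trends of annual VPD, relative
   trends, double-hazard masks (joint-median or high-PWS × above-average
   trend), and wildland-urban-interface (WUI) population change by hazard
   zone.

Every stage is exercised on synthetic grids generated by the package
itself (`syntheticTruth()`, `simulateClimate()`, `simulateLfmc()`,
`simulateFire()`, `simulateTraits()`, `simulateWui()`), each with a
recorded ground truth for parameter-recovery tests.

## Worked example

```r
library(pwsfire)

grid  <- gridDef(32, 32)                                  # 4-km-style grid
truth <- syntheticTruth(grid, seed = 42)                  # known kernels, PWS*, slope law
clim  <- simulateClimate(grid, years = 2015:2020, seed = 42)
lfmc  <- simulateLfmc(clim$dfmc, truth, targetR2 = 0.3, seed = 42)

pws <- estimatePwsMap(lfmc, clim$dfmc, lagConfig())
pws
#> PWSMap: 1024 / 1024 valid pixels; PWS median 1.174 [0.001, 4.152]; median fit R2 0.309
cor(pwsValues(pws), truePws(truth))
#> [1] 0.8821266

vpdAnnual <- fireYearAggregate(clim$vpd, 4, "mean")       # April-March fire years
ba    <- simulateFire(truth, vpdAnnual, seed = 42)
bins  <- equalAreaBins(pws, k = 15)
curve <- sensitivityCurve(bins, binSlopes(binAnnualSeries(ba, vpdAnnual, bins)))
curve$coefficient
#> [1] 107.7819

classifyHazard(pws)
#> HazardMap (thresholds 1.00 / 1.50): low 432, medium 221, high 371 pixels
```

The fit diagnostics say the noise calibration worked (median per-pixel
regression R² ≈ 0.31, the intended study condition) and the estimated map
tracks the generating PWS closely (r = 0.88). The slope-vs-PWS coefficient
of 108 km² hPa⁻¹ per PWS unit is attenuated relative to the generating
value of 175 because the bins are built from the *noisy* PWS estimates —
ordinary errors-in-variables dilution; rerunning with `noiseSd = 0` in
`simulateLfmc()` recovers the generating coefficient to within a few
percent. `runPipeline()` chains all stages (including trait attribution,
VPD trends, double hazard and WUI exposure) from one configuration and
writes CSV outputs plus a JSON report.

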