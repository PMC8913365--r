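---
title: "Plant-water sensitivity and wildfire vulnerability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant-water sensitivity and wildfire vulnerability: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical model behind plant-water sensitivity (PWS), the downstream
hazard and exposure analyses, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
method leaves room.

## The PWS model

Live fuel moisture content (LFMC, % water per dry biomass) integrates a
plant's hydraulic response to climatic water supply and demand. The
package represents the climate side by dead fuel moisture content (DFMC,
the 100-h meteorological wetness index), and asks, per pixel `s`: how much
does an anomaly in climate-derived moisture balance move the live fuel
moisture, now and over the preceding five months?

The working model is a distributed-lag regression on half-monthly epochs

$$\mathrm{LFMC}'_{s,t} = \sum_{i = 0,15,\dots,150} \beta_{s,i}\,
  \mathrm{DFMC}'_{s,t-i} + \gamma_s, \qquad \beta_{s,i} \ge 0,$$

with plant-water sensitivity defined as the unweighted coefficient sum
$\mathrm{PWS}_s = \sum_i \beta_{s,i}$, so concurrent and antecedent
conditions count equally. Primes denote anomalies: raw values minus the
pixel-specific epoch-of-year climatology, which removes spatially varying
seasonality so that only departures from the local seasonal norm drive the
fit. The non-negativity constraint encodes the physical prior that a
wetter climate cannot dry live fuels; its side effect is sparsity (many
coefficients sit exactly on the boundary), which is why the per-pixel
`zeroFraction` is reported.

Assumptions worth keeping in mind: the response is linear in the anomaly
range observed; lags beyond 150 d carry no information (a soil-moisture
memory horizon); and the June–November window isolates climatic dry-down
from spring growth dynamics.

### Estimation choices

* **Solver.** Exact Lawson–Hanson active-set non-negative least squares
  (`nnlsFit()`), deterministic, dual-feasibility tolerance `1e-10` scaled
  by the gradient magnitude. With 11 columns the active-set iteration is
  exact and fast; the test suite checks it against full active-set
  enumeration (2^k subsets) and against an independent library
  implementation.
* **Intercept.** $\gamma_s$ must stay unconstrained. Centring the response
  and the design columns before the non-negative solve and back-computing
  $\gamma_s = \bar y - \bar x \cdot \beta$ achieves this exactly.
* **Record and masking.** Defaults (`lagConfig()`): lags 0–150 d in 15-d
  steps, June–November, five years, so a complete record has 60 rows for
  11 coefficients plus intercept. A pixel is masked when more than 50% of
  its seasonal LFMC record is missing (strictly more: a pixel at exactly
  half valid is kept), or when fewer than `pMin = 30` rows survive
  listwise deletion — about 2.7 observations per parameter, consistent
  with tolerating 50% loss. Rows with any missing lagged predictor are
  dropped, not imputed.
* **Climatologies.** Keyed by epoch-of-year (24 half-monthly bins: days
  1–15 and 16–end of each month), computed over the regression years, with
  `minYears = 2` — a one-year "climatology" would force that year's
  anomalies to zero. The predictor climatology uses all epochs of those
  years, not only June–November, because lags reach back up to 150 d
  before the season; within this window a lagged epoch never crosses a
  year boundary, which is what makes noise-free parameter recovery exact.
* **R².** Computed against the response mean and clipped at zero with a
  flag; with a free intercept the unclipped value cannot actually drop
  below zero, so the clip only guards degenerate inputs. A constant
  response yields `NA` with a flag rather than a fabricated fit quality.

## From PWS to burned-area sensitivity

Burned area cannot be regressed on VPD per pixel — most pixels never burn
in a given year — so pixels of similar PWS are pooled: sort vegetated
pixels by PWS, split the cumulative vegetated area into `k = 15` bins
(largest-minus-smallest bin area is at most one pixel; ties broken by
pixel index), and per bin aggregate annual burned area as a sum and annual
VPD as a vegetated-area-weighted mean over April–March fire years. Per
bin, an ordinary least-squares slope d(BA)/d(VPD) with its classical
standard error; across bins, an unweighted OLS of those slopes on the
bins' representative PWS (area-weighted mean by default, median as an
option). The displayed per-bin standard errors are not used as weights in
the final regression.

One scaling property matters when varying `k`: per-bin burned area is a
*sum* over member pixels, so the slope and hence the final coefficient
scale with the area per bin, i.e. inversely with `k`. Robustness
comparisons between 10 and 15 bins therefore compare `k`-scaled
coefficients; the package's synthetic slope law is anchored at the 15-bin
aggregation scale.

Hazard classes follow the empirical shape of the slope-vs-PWS relation:
low for PWS < 1, high for PWS > 1.5, medium for the closed interval
between — the only exhaustive, non-overlapping reading of the three
classes; the thresholds are arguments, not constants. The percent-change
variant transforms each bin's series to 100·(BA − BA₀)/BA₀ relative to a
baseline year before the slope, making it invariant to bin size.

## Trait attribution

`fitTraitImportance()` regresses the PWS map on 14 static plant and soil
hydraulic trait maps (saturated soil conductivity, retention-curve shape,
porosity, sand/silt/clay fractions, canopy height, xylem capacitance,
stomatal slope g₁, maximum xylem conductance, ψ₅₀, hydraulic functional
type, isohydricity, rooting depth) with a random-forest ensemble: 50
trees, minimum terminal-node size 6, per-tree bootstrap resampling, and
normalised mean-impurity-decrease importance, with 3-fold cross-validated
out-of-sample R². Choices:

* **Candidate features per split.** All traits are candidates at every
  split (`mtry` = trait count), the standard regression-forest default in
  the ensemble library this analysis style comes from. Restricting
  candidates to √p smears impurity credit over irrelevant traits: in the
  closed-loop test a noiselessly generating trait then earns only ~0.67
  importance instead of > 0.9.
* **Unexposed thresholds.** The underlying `ranger` engine does not expose
  a minimum impurity decrease per split; at the conventional threshold of
  5·10⁻⁶ — vanishingly small against the PWS variance — its absence does
  not change the trees materially.
* **Categorical traits** (hydraulic functional type) stay integer-coded
  rather than one-hot, so each trait carries exactly one importance.
* **Folds** are random pixel partitions. Spatial autocorrelation makes
  random-fold CV optimistic on real maps; treat the CV R² as an
  upper-bound fit measure.
* **Missing data:** traits missing on more than half the pixels are
  excluded with a warning; remaining gaps are handled by listwise
  deletion, with the pixel count reported.

## Trends, double hazard and WUI exposure

Per-pixel VPD trends are OLS slopes of annual means against year (at least
10 years), with relative trends dividing by the pixel's long-term mean.
Double hazard marks pixels high in both PWS and VPD trend, either as both
above their medians (computed over jointly valid pixels — joint validity
avoids mask-induced bias) or as PWS ≥ 1.5 with a trend above the spatial
mean (median switchable). Under independent continuous fields the
joint-median fraction converges to 1/4, a limit the acceptance suite
checks at 100,000 pixels.

WUI exposure sums per-pixel populations over wildland-urban-interface
pixels by hazard zone for two census epochs and reports percent change
(one decimal, flagged rather than infinite when a zone starts empty) and
zone shares per epoch, which sum to one by construction.

## The synthetic generator, and what passing tests do not show

Generators (all bit-reproducible given their arguments and a seed):

* **Climate** (`simulateClimate()`): pixel-specific seasonal cycles plus
  AR(1) anomalies (lag-1 autocorrelation 0.7 at the half-monthly step;
  DFMC anomaly sd 2.5%, VPD 1.2 hPa), a VPD component anticorrelated with
  DFMC (weight 0.4), a common interannual VPD offset (sd 1 hPa) that
  provides the year-to-year variation the slope regressions need, and an
  optional per-pixel linear VPD trend.
* **LFMC** (`simulateLfmc()`): the lag model run forward — seasonal cycle
  plus the kernel convolution of DFMC anomalies plus Gaussian noise. True
  kernels are sparse exponentials (each lag active with probability 1/2)
  scaled so true PWS follows a spatially smooth field, uniform on [0, 2].
  `targetR2` calibrates noise to a target *in-sample* fit R² of the
  downstream regression (default 0.3, the study condition): because an
  11-lag fit on 60 rows inflates in-sample R², the generating
  signal-to-total ratio is set to
  `1 − (1 − targetR2)·(n − 1)/(n − 1 − p_eff)` with `n = 60` nominal rows
  and `p_eff = 7` effective parameters (about half the constrained slopes
  active, plus the intercept); the acceptance suite verifies the achieved
  median lands within ±0.05 of the target.
* **Fire** (`simulateFire()`): per pixel-year,
  `BA = max(0, (a + b·PWS)·VPD/areaNorm + ε)` with `a = 350`,
  `b = 175` km² hPa⁻¹ so expected 15-bin slopes span 350–700 km² hPa⁻¹
  over PWS ∈ [0, 2]; `areaNorm` defaults to one fifteenth of the pixels,
  anchoring the law at the 15-bin scale. Pixel-year noise sd 1 km²;
  clipping at zero is rare by construction and warned about when the
  expected value itself goes negative.
* **Traits** (`simulateTraits()`): linear-plus-noise functions of
  block-averaged PWS at a coarser resolution (default 8×8 blocks,
  mimicking 25-km trait products against a 4-km analysis grid), then
  nearest-neighbour upsampled; soil fractions squashed into [0, 1], the
  functional type quartile-coded.
* **WUI** (`simulateWui()`): a WUI mask over 30% of each hazard zone,
  lognormal 1990 populations with fixed zone shares, zone growth factors
  2.07/1.95/2.60 with optional lognormal jitter. The default shares are
  the exact algebraic solution under which those zone growths produce a
  108% total rise; the printed zone growths and totals jointly determine
  them.

The standard fixture is a 64 × 64 grid over 2015–2020 (five regression
years after lag spin-up) with seed 42 — sized so the full suite and the
acceptance script run in seconds on one CPU while leaving ~4,100 pixels
and 60-row regressions, ample for the tolerances tested.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: spatially coherent fire events (pixel-year
noise is independent Gaussian, not spreading fires), non-Gaussian burned
area (real BA is zero-inflated and heavy-tailed), cloud/snow missingness
structure (gaps are uniform at random), retrieval error in LFMC beyond
white noise, real geography or land-cover composition, and observational
error in the trait maps beyond block-level noise. The closed loops
demonstrate that the estimators recover what the model generates; they do
not validate the model against nature.

## Known limitations and behaviour at the edges

* Binning on *estimated* PWS attenuates the slope-vs-PWS coefficient
  through classical errors-in-variables dilution; at the calibrated noise
  level the recovered coefficient is substantially below the generating
  one, which is why low-noise runs are used for slope-law recovery checks.
  Any real-data application inherits the same attenuation.
* The constraint induces a positive bias in PWS under pure noise
  (truncation at zero), growing with the noise-to-predictor ratio: a
  zero-kernel pixel shows near-zero estimated PWS only when the response
  noise is small relative to predictor variability.
* Sign-flipping the whole 11-lag predictor does not drive every
  coefficient exactly to zero in finite samples — chance-positive partial
  correlations among autocorrelated lags survive — though the estimated
  PWS collapses to a small fraction of its baseline.
* Equal-area binning guarantees the one-pixel balance bound only for
  uniform pixel areas; with strongly non-uniform areas the greedy
  cumulative split can deviate by up to the largest single pixel.
* File I/O uses the package's plain-text CSV dialects (metadata header
  plus value matrix; long format for epoch stacks); the in-memory classes,
  not the files, carry the analysis.
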