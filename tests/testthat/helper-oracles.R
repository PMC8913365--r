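# Independent oracles and shared fixtures.

# Brute-force non-negative least squares: enumerate every active set,
# solve the unconstrained subproblem, keep feasible candidates, return the
# best objective. Independent of the active-set solver under test.
bruteNnls <- function(X, y) {
  p <- ncol(X)
  best <- sum(y^2)           # empty active set (beta = 0)
  bestBeta <- numeric(p)
  for (mask in seq_len(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    Xs <- X[, S, drop = FALSE]
    b <- tryCatch(qr.coef(qr(Xs), y), error = function(e) NULL)
    if (is.null(b) || anyNA(b) || any(b < -1e-12)) next
    obj <- sum((y - Xs %*% b)^2)
    if (obj < best) {
      best <- obj
      bestBeta <- numeric(p)
      bestBeta[S] <- b
    }
  }
  list(beta = bestBeta, objective = best)
}

randomNnlsProblem <- function(maxCols = 11) {
  p <- sample.int(maxCols, 1)
  n <- sample(15:40, 1)
  X <- matrix(rnorm(n * p), n, p)
  beta <- ifelse(runif(p) < 0.5, 0, runif(p, 0, 2)) *
    sample(c(1, -1), p, replace = TRUE, prob = c(0.7, 0.3))
  y <- drop(X %*% beta) + rnorm(n, sd = runif(1, 0.1, 2))
  list(X = X, y = y)
}

# Standard 64 x 64 / 6-year / seed-42 fixture, built once per test run.
.fixtureCache <- new.env(parent = emptyenv())

standardFixture <- function() {
  if (!is.null(.fixtureCache$std)) return(.fixtureCache$std)
  grid <- gridDef(64, 64)
  truth <- syntheticTruth(grid, seed = 42)
  clim <- simulateClimate(grid, years = 2015:2020, seed = 42)
  lfmc <- simulateLfmc(clim$dfmc, truth, targetR2 = 0.3, seed = 42)
  pws <- estimatePwsMap(lfmc, clim$dfmc, lagConfig())
  .fixtureCache$std <- list(grid = grid, truth = truth, clim = clim,
                            lfmc = lfmc, pws = pws)
  .fixtureCache$std
}

# Noise-free variant on a smaller grid: exact parameter recovery.
noiseFreeFixture <- function() {
  if (!is.null(.fixtureCache$nf)) return(.fixtureCache$nf)
  grid <- gridDef(16, 16)
  truth <- syntheticTruth(grid, seed = 42)
  clim <- simulateClimate(grid, years = 2015:2020, seed = 42)
  lfmc <- simulateLfmc(clim$dfmc, truth, noiseSd = 0, seed = 42)
  pws <- estimatePwsMap(lfmc, clim$dfmc, lagConfig())
  .fixtureCache$nf <- list(grid = grid, truth = truth, clim = clim,
                           lfmc = lfmc, pws = pws)
  .fixtureCache$nf
}

# Low-noise fire fixture at the standard scale: noise-free LFMC so the PWS
# map is exact, with the default burned-area noise.
lowNoiseFireFixture <- function() {
  if (!is.null(.fixtureCache$fire)) return(.fixtureCache$fire)
  grid <- gridDef(64, 64)
  truth <- syntheticTruth(grid, seed = 42)
  clim <- simulateClimate(grid, years = 2015:2020, seed = 42)
  lfmc <- simulateLfmc(clim$dfmc, truth, noiseSd = 0, seed = 42)
  pws <- estimatePwsMap(lfmc, clim$dfmc, lagConfig())
  vpdAnnual <- fireYearAggregate(clim$vpd, 4, "mean")
  ba <- simulateFire(truth, vpdAnnual, seed = 42)
  .fixtureCache$fire <- list(grid = grid, truth = truth, pws = pws,
                             vpdAnnual = vpdAnnual, ba = ba)
  .fixtureCache$fire
}
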