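## Attribute spatial PWS variance to plant and soil hydraulic traits with a
## random-forest regression: 50 trees, minimum terminal-node size 6,
## bootstrap resampling per tree, impurity-based importance normalised to
## sum 1, and 3-fold cross-validated R2 for the strength of fit.

#' Trait importance for PWS via random-forest regression
#'
#' Trains a regression forest of `(trait vector -> PWS)` on all pixels with
#' a valid PWS and a complete trait vector (listwise deletion; traits with
#' more than `maxMissing` missing share are excluded with a warning).
#' Importance is the normalised mean decrease in node impurity; fit quality
#' is reported as k-fold cross-validated R2 on random pixel partitions.
#' Deterministic given `seed`.
#'
#' @param traits a [RasterStack-class] of trait maps, or a data frame /
#'   matrix of per-pixel trait columns. Categorical traits (e.g. hydraulic
#'   functional type) are integer-coded, not one-hot.
#' @param pws a [PWSMap-class] or numeric per-pixel PWS vector.
#' @param numTrees trees in the forest (default 50).
#' @param minNodeSize minimum terminal-node size (default 6).
#' @param mtry candidate traits per split; `NULL` (default) tries every
#'   trait at every split, the usual regression-forest default.
#' @param folds cross-validation folds (default 3).
#' @param seed integer seed controlling the forest and the fold partition.
#' @param maxMissing maximum tolerated missing share per trait (default
#'   0.5).
#' @return list with `importance` (named, non-negative, sums to 1),
#'   `cvR2` (per-fold out-of-sample R2), `nUsed` (pixels fit), `excluded`
#'   (trait names dropped for missingness), `hyperparameters` and `seed`.
#' @export
fitTraitImportance <- function(traits, pws, numTrees = 50, minNodeSize = 6,
                               mtry = NULL, folds = 3, seed = 1,
                               maxMissing = 0.5) {
  X <- if (is(traits, "RasterStack"))
    as.data.frame(lapply(traits@layers, asPixelVector))
  else as.data.frame(traits)
  y <- if (is(pws, "PWSMap")) pwsValues(pws) else as.numeric(pws)
  stopifnot(nrow(X) == length(y))
  missShare <- vapply(X, function(col) mean(is.na(col)), numeric(1))
  if (all(missShare >= 1)) stop("all traits are entirely missing")
  excluded <- names(X)[missShare > maxMissing]
  if (length(excluded)) {
    warning(sprintf("excluding traits with > %.0f%% missing pixels: %s",
                    100 * maxMissing, paste(excluded, collapse = ", ")))
    X <- X[setdiff(names(X), excluded)]
  }
  keep <- !is.na(y) & rowSums(is.na(X)) == 0L
  if (sum(keep) < 100)
    stop(sprintf("only %d complete pixels; need at least 100", sum(keep)))
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (is.null(mtry)) mtry <- ncol(X)

  rf <- ranger::ranger(x = X, y = y, num.trees = numTrees,
                       min.node.size = minNodeSize, mtry = mtry,
                       importance = "impurity", replace = TRUE, seed = seed)
  imp <- rf$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)

  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), length(y)))
  cvR2 <- vapply(seq_len(folds), function(f) {
    train <- fold != f
    m <- ranger::ranger(x = X[train, , drop = FALSE], y = y[train],
                        num.trees = numTrees, min.node.size = minNodeSize,
                        mtry = mtry, replace = TRUE, seed = seed + f)
    pred <- stats::predict(m, data = X[!train, , drop = FALSE])$predictions
    obs <- y[!train]
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }, numeric(1))

  list(importance = imp, cvR2 = cvR2, nUsed = length(y), excluded = excluded,
       hyperparameters = list(numTrees = numTrees, minNodeSize = minNodeSize,
                              mtry = mtry, folds = folds),
       seed = seed)
}
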