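## Regridding between GridDefs. All stages of the pipeline operate on one
## shared analysis grid; regrid() moves source products onto it with the
## method appropriate to the quantity (interpolation for intensive fields,
## block sums for areas, any-overlap for masks).

gridExtent <- function(g) {
  c(xmin = g@x0, xmax = g@x0 + g@nCol * g@dx,
    ymin = g@y0 - g@nRow * g@dy, ymax = g@y0)
}

cellCentersX <- function(g) g@x0 + (seq_len(g@nCol) - 0.5) * g@dx
cellCentersY <- function(g) g@y0 - (seq_len(g@nRow) - 0.5) * g@dy

describeGrid <- function(g) {
  sprintf("%dx%d grid at (%g,%g) spacing (%g,%g)", g@nRow, g@nCol, g@x0, g@y0, g@dx, g@dy)
}

checkExtents <- function(source, target, tol = 1e-9) {
  es <- gridExtent(source); et <- gridExtent(target)
  if (et["xmin"] < es["xmin"] - tol || et["xmax"] > es["xmax"] + tol ||
      et["ymin"] < es["ymin"] - tol || et["ymax"] > es["ymax"] + tol)
    stop(sprintf("incompatible extents: target [%s] not contained in source [%s]",
                 describeGrid(target), describeGrid(source)))
}

blockFactors <- function(source, target, tol = 1e-9) {
  checkExtents(source, target, tol)
  es <- gridExtent(source); et <- gridExtent(target)
  if (any(abs(es - et) > tol))
    stop(sprintf("block regridding needs identical extents: source [%s] vs target [%s]",
                 describeGrid(source), describeGrid(target)))
  fR <- source@nRow / target@nRow
  fC <- source@nCol / target@nCol
  if (abs(fR - round(fR)) > tol || abs(fC - round(fC)) > tol || fR < 1 || fC < 1)
    stop(sprintf("block regridding needs an integer coarsening ratio: source [%s] vs target [%s]",
                 describeGrid(source), describeGrid(target)))
  c(round(fR), round(fC))
}

## Aggregate an nR x nC matrix into (nR/fR) x (nC/fC) blocks.
blockAggregate <- function(m, fR, fC, what = c("sum", "mean", "any")) {
  what <- match.arg(what)
  nRt <- nrow(m) %/% fR; nCt <- ncol(m) %/% fC
  acc <- matrix(0, nRt, nCt)
  cnt <- matrix(0L, nRt, nCt)
  anyTrue <- matrix(FALSE, nRt, nCt)
  for (i in seq_len(fR)) for (j in seq_len(fC)) {
    sub <- m[seq(i, by = fR, length.out = nRt), seq(j, by = fC, length.out = nCt), drop = FALSE]
    ok <- !is.na(sub)
    acc[ok] <- acc[ok] + sub[ok]
    cnt <- cnt + ok
    anyTrue <- anyTrue | (ok & sub != 0)
  }
  if (what == "any") {
    out <- anyTrue
    out[cnt == 0L] <- NA
    return(out + 0)  # numeric 0/1 with NA for nodata-only blocks
  }
  out <- acc
  out[cnt == 0L] <- NA
  if (what == "mean") out <- out / cnt
  out
}

interpIndex <- function(coordTarget, origin, spacing, n, sign = 1) {
  ## fractional 0-based cell-centre index of target coords on the source axis
  u <- sign * (coordTarget - origin) / spacing - 0.5
  pmin(pmax(u, 0), n - 1)
}

regridMatrix <- function(m, source, target, method) {
  if (method %in% c("block_mean", "block_sum", "any_overlap")) {
    f <- blockFactors(source, target)
    what <- switch(method, block_mean = "mean", block_sum = "sum", any_overlap = "any")
    return(blockAggregate(m, f[1], f[2], what))
  }
  checkExtents(source, target)
  xs <- cellCentersX(target); ys <- cellCentersY(target)
  u <- interpIndex(xs, source@x0, source@dx, source@nCol)          # columns
  v <- interpIndex(ys, source@y0, source@dy, source@nRow, sign = -1)  # rows
  if (method == "nearest") {
    ri <- round(v) + 1L; ci <- round(u) + 1L
    return(matrix(m[cbind(rep(ri, times = length(ci)), rep(ci, each = length(ri)))],
                  target@nRow, target@nCol))
  }
  ## bilinear
  c0 <- pmin(floor(u), source@nCol - 2L); fu <- u - c0
  r0 <- pmin(floor(v), source@nRow - 2L); fv <- v - r0
  if (source@nCol == 1L) { c0 <- rep(0L, length(u)); fu <- rep(0, length(u)) }
  if (source@nRow == 1L) { r0 <- rep(0L, length(v)); fv <- rep(0, length(v)) }
  R0 <- rep(r0 + 1L, times = target@nCol); FV <- rep(fv, times = target@nCol)
  C0 <- rep(c0 + 1L, each = target@nRow); FU <- rep(fu, each = target@nRow)
  C1 <- pmin(C0 + 1L, source@nCol); R1 <- pmin(R0 + 1L, source@nRow)
  a <- m[cbind(R0, C0)]; b <- m[cbind(R0, C1)]
  cc <- m[cbind(R1, C0)]; d <- m[cbind(R1, C1)]
  val <- (1 - FV) * ((1 - FU) * a + FU * b) + FV * ((1 - FU) * cc + FU * d)
  matrix(val, target@nRow, target@nCol)
}

#' Regrid a raster stack onto a target grid
#'
#' Supported methods: `bilinear` and `nearest` interpolation at cell centres
#' (units preserved; bilinear propagates `NA` from any contributing source
#' cell), `block_mean` and `block_sum` aggregation for integer coarsening
#' ratios (ignoring `NA` cells; a block with no valid cell becomes `NA`;
#' `block_sum` conserves the global sum over valid cells), and `any_overlap`
#' which returns 1 where at least one source cell in the block is nonzero
#' (for boolean masks such as wildland-urban-interface rasters).
#'
#' @param source a [RasterStack-class].
#' @param target a [GridDef-class] contained in the source extent.
#' @param method one of `"bilinear"`, `"nearest"`, `"block_mean"`,
#'   `"block_sum"`, `"any_overlap"`.
#' @return A [RasterStack-class] on `target` with the same layer names and
#'   units tag.
#' @examples
#' src <- gridDef(4, 4, dx = 1, dy = 1)
#' tgt <- gridDef(2, 2, dx = 2, dy = 2)
#' chk <- matrix(as.numeric((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2), 4, 4)
#' regrid(rasterStack(src, list(x = chk)), tgt, "block_mean")
#' @export
setGeneric("regrid", function(source, target, method) standardGeneric("regrid"))

#' @rdname regrid
setMethod("regrid", signature("RasterStack", "GridDef"), function(source, target, method) {
  method <- match.arg(method, c("bilinear", "nearest", "block_mean", "block_sum", "any_overlap"))
  out <- lapply(source@layers, regridMatrix, source = source@grid,
                target = target, method = method)
  rasterStack(target, out, units = source@units)
})

#' Pixel-vector / matrix conversion helpers
#'
#' Pixels are stored row-major: `asPixelVector` flattens an `nRow x nCol`
#' matrix into the pixel order used by [EpochSeries-class] and
#' [PWSMap-class]; `asGridMatrix` is the inverse.
#' @param m matrix (for `asPixelVector`) or per-pixel vector (for
#'   `asGridMatrix`).
#' @param grid the [GridDef-class].
#' @return numeric vector or matrix.
#' @export
asPixelVector <- function(m) as.vector(t(m))

#' @rdname asPixelVector
#' @param v per-pixel vector in row-major order.
#' @export
asGridMatrix <- function(v, grid) matrix(v, grid@nRow, grid@nCol, byrow = TRUE)
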