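## Plain-text I/O. Single maps and stacks are written as CSV with a short
## metadata header (lines starting with "#") carrying the grid definition,
## units and the nodata sentinel, so files round-trip without side channels.

writeGridHeader <- function(con, grid, units, nodata) {
  writeLines(c(
    sprintf("# nrow=%d ncol=%d pixel_area=%.10g", grid@nRow, grid@nCol, grid@pixelArea),
    sprintf("# x0=%.10g y0=%.10g dx=%.10g dy=%.10g", grid@x0, grid@y0, grid@dx, grid@dy),
    sprintf("# units=%s nodata=%.10g", units, nodata)), con)
}

parseGridHeader <- function(lines) {
  kv <- unlist(regmatches(lines, gregexpr("[a-z_0-9]+=[^ ]+", lines)))
  vals <- sub("^[^=]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  list(grid = gridDef(as.integer(vals["nrow"]), as.integer(vals["ncol"]),
                      pixelArea = as.numeric(vals["pixel_area"]),
                      x0 = as.numeric(vals["x0"]), y0 = as.numeric(vals["y0"]),
                      dx = as.numeric(vals["dx"]), dy = as.numeric(vals["dy"])),
       units = unname(vals["units"]), nodata = as.numeric(vals["nodata"]))
}

#' Write / read a single gridded map as CSV
#'
#' The file holds a three-line metadata header (grid shape, coordinates,
#' units, nodata sentinel) followed by the `nRow x nCol` value matrix, one
#' grid row per CSV line. `NA` cells are written as the nodata sentinel,
#' which must lie outside the valid data range.
#'
#' @param values matrix (`nRow x nCol`) or per-pixel vector in row-major
#'   order.
#' @param grid the [GridDef-class].
#' @param path output file.
#' @param units units tag.
#' @param nodata nodata sentinel written in place of `NA`.
#' @return `writeGridCsv` returns `path` invisibly; `readGridCsv` returns a
#'   list with elements `values` (matrix with `NA` restored), `grid`,
#'   `units`.
#' @export
writeGridCsv <- function(values, grid, path, units = "1", nodata = -9999) {
  m <- if (is.matrix(values)) values else asGridMatrix(values, grid)
  if (any(!is.na(m) & m == nodata))
    stop("nodata sentinel collides with valid data; choose another sentinel")
  m[is.na(m)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeGridHeader(con, grid, units, nodata)
  utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGridCsv
#' @export
readGridCsv <- function(path) {
  lines <- readLines(path)
  hdr <- parseGridHeader(lines[1:3])
  m <- as.matrix(utils::read.csv(text = lines[-(1:3)], header = FALSE))
  dimnames(m) <- NULL
  m[m == hdr$nodata] <- NA
  stopifnot(nrow(m) == hdr$grid@nRow, ncol(m) == hdr$grid@nCol)
  list(values = m, grid = hdr$grid, units = hdr$units)
}

#' Write / read an epoch series as long-format CSV
#'
#' One row per (epoch, pixel) with columns `year, month, eoy, pixel, value`;
#' the grid metadata travels in the same commented header as
#' [writeGridCsv()]. Missing values are dropped on write and restored as
#' `NA` on read.
#'
#' @param x an [EpochSeries-class].
#' @param path output file.
#' @return `writeEpochSeriesCsv` returns `path` invisibly;
#'   `readEpochSeriesCsv` returns an [EpochSeries-class].
#' @export
writeEpochSeriesCsv <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeGridHeader(con, x@grid, x@units, -9999)
  cal <- x@calendar
  df <- data.frame(year = rep(cal$year, each = nrow(x@values)),
                   month = rep(cal$month, each = nrow(x@values)),
                   eoy = rep(cal$eoy, each = nrow(x@values)),
                   pixel = rep(seq_len(nrow(x@values)), times = nrow(cal)),
                   value = as.vector(x@values))
  df <- df[!is.na(df$value), ]
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEpochSeriesCsv
#' @export
readEpochSeriesCsv <- function(path) {
  lines <- readLines(path)
  hdr <- parseGridHeader(lines[1:3])
  df <- utils::read.csv(text = lines[-(1:3)])
  cal <- epochCalendar(sort(unique(df$year)))
  vals <- matrix(NA_real_, nPixels(hdr$grid), nrow(cal))
  epochKey <- match(paste(df$year, df$eoy), paste(cal$year, cal$eoy))
  vals[cbind(df$pixel, epochKey)] <- df$value
  epochSeries(hdr$grid, vals, cal, units = hdr$units)
}

#' Write a data frame as a CSV table with header row
#' @param df data frame.
#' @param path output file.
#' @return `path` invisibly.
#' @export
writeTableCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
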