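#' Create a grid descriptor
#'
#' @param xmin,xmax,ymin,ymax extent in decimal degrees.
#' @param res cell size in degrees.
#' @return a [GridSpec-class].
#' @examples
#' gridSpec4326(-20, 20, -20, 20, 0.25)
#' @export
gridSpec4326 <- function(xmin, xmax, ymin, ymax, res) {
  new("GridSpec", xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
      res = res)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a [GridSpec-class].
#' @return list with `lon` (length `nCols`) and `lat` (length `nRows`)
#'   center coordinates, ascending.
#' @export
cellCenters <- function(grid) {
  list(lon = grid@xmin + (seq_len(nCols(grid)) - 0.5) * grid@res,
       lat = grid@ymin + (seq_len(nRows(grid)) - 0.5) * grid@res)
}

#' Map coordinates to grid row/column indices
#'
#' Cells are half-open `[lo, hi)`: a point on a cell's west/south edge maps
#' to that cell. Points outside the extent get `NA` indices.
#'
#' @param grid a [GridSpec-class].
#' @param lon,lat coordinate vectors (recycled to common length).
#' @return data.frame with integer columns `row`, `col`.
#' @export
cellIndexOf <- function(grid, lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  col <- floor((lon - grid@xmin) / grid@res) + 1L
  row <- floor((lat - grid@ymin) / grid@res) + 1L
  bad <- lon < grid@xmin | lon >= grid@xmax | lat < grid@ymin |
    lat >= grid@ymax
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Aggregate a fine-grid raster onto a coarser grid
#'
#' Each fine cell is assigned to the coarse cell containing its center; the
#' coarse value is the mean of the assigned fine values (`NA` removed; a
#' coarse cell with no non-missing fine cells is `NA`). This handles
#' resolution ratios that are not whole numbers, such as 0.1 to 0.25
#' degrees.
#'
#' @param values fine-grid numeric matrix.
#' @param from fine [GridSpec-class] matching `values`.
#' @param to coarse [GridSpec-class]; must share the extent of `from` and
#'   have `res` strictly greater.
#' @return matrix on the `to` grid.
#' @export
blockAggregate <- function(values, from, to) {
  if (from@xmin != to@xmin || from@xmax != to@xmax ||
      from@ymin != to@ymin || from@ymax != to@ymax)
    stop("grids must share an identical extent")
  if (to@res <= from@res)
    stop("target grid must be coarser than the source grid")
  cc <- cellCenters(from)
  colMap <- floor((cc$lon - to@xmin) / to@res) + 1L
  rowMap <- floor((cc$lat - to@ymin) / to@res) + 1L
  nyt <- nRows(to); nxt <- nCols(to)
  # accumulate sums and counts per coarse cell, ignoring NA
  idx <- (rep(colMap, each = length(rowMap)) - 1L) * nyt +
    rep(rowMap, times = length(colMap))
  v <- as.vector(values)
  ok <- !is.na(v)
  sums <- rep(0, nyt * nxt); cnts <- rep(0L, nyt * nxt)
  if (any(ok)) {
    s <- tapply(v[ok], idx[ok], sum)
    n <- tapply(rep(1L, sum(ok)), idx[ok], sum)
    sums[as.integer(names(s))] <- s
    cnts[as.integer(names(n))] <- n
  }
  out <- sums / cnts
  out[cnts == 0L] <- NA_real_
  matrix(out, nrow = nyt, ncol = nxt)
}

#' Aggregate a logical mask onto a coarser grid (majority rule)
#'
#' @inheritParams blockAggregate
#' @param values logical matrix.
#' @return logical matrix on the `to` grid; TRUE where at least half the
#'   contributing fine cells are TRUE.
#' @export
blockAggregateMask <- function(values, from, to) {
  frac <- blockAggregate(values * 1, from, to)
  out <- frac >= 0.5
  out[is.na(frac)] <- NA
  out
}

gridsIdentical <- function(a, b) {
  isTRUE(all.equal(c(a@xmin, a@xmax, a@ymin, a@ymax, a@res),
                   c(b@xmin, b@xmax, b@ymin, b@ymax, b@res)))
}
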