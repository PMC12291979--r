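#' Bring shipping density onto the suitability grid
#'
#' The fine-grid density index is block-aggregated (mean of the fine cells
#' whose centers fall in each coarse cell) onto the suitability map's
#' grid. Aggregation preserves the `[0, 1]` range; the suitability map is
#' untouched, since it carries no sub-cell information to interpolate.
#'
#' @param vi a [DensityIndex-class] on the fine grid.
#' @param di a [SuitabilityMap-class] on the coarse grid (same extent).
#' @return list with `vi` (a coarse-grid [DensityIndex-class]) and `di`.
#' @export
alignGrids <- function(vi, di) {
  gf <- vi@grid; gc <- gridSpec(di)
  if (gf@xmax <= gc@xmin || gc@xmax <= gf@xmin ||
      gf@ymax <= gc@ymin || gc@ymax <= gf@ymin)
    stop("disjoint extents: the grids do not overlap")
  if (gridsIdentical(gf, gc)) return(list(vi = vi, di = di))
  agg <- blockAggregate(vi@values, gf, gc)
  list(vi = new("DensityIndex", values = agg, grid = gc,
                name = vi@name, floorHours = vi@floorHours,
                maxLog = vi@maxLog),
       di = di)
}

#' Collision risk Ri = Vi x Di
#'
#' Cellwise product of the shipping density index and the habitat
#' suitability, on a shared grid; missing cells in either input propagate.
#'
#' @param vi a [DensityIndex-class].
#' @param di a [SuitabilityMap-class] on the same grid.
#' @return a [RiskMap-class].
#' @export
computeRisk <- function(vi, di) {
  g <- gridSpec(di)
  if (!gridsIdentical(vi@grid, g))
    stop("grid mismatch: align the grids first (see alignGrids)")
  ri <- vi@values * gridValues(di)
  new("RiskMap", values = ri, grid = g, name = "collision_risk",
      speciesId = di@speciesId,
      provenance = c(vi = vi@name, di = di@di@name))
}

#' Extract the percentile hotspot mask of a risk map
#'
#' The threshold is the stated quantile (linear-interpolation convention)
#' of the non-missing risk values; flagged cells satisfy `ri >= threshold`
#' (inclusive, so the "top 1%" of a 99th-percentile mask includes ties at
#' the threshold). Percentiles are computed over valid (sea) cells only.
#'
#' @param risk a [RiskMap-class].
#' @param percentile percentile in (0, 100); the conventional set is
#'   90, 95, 99, 99.5.
#' @return a [HotspotMask-class].
#' @export
hotspotMask <- function(risk, percentile = 99) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  v <- risk@values
  valid <- !is.na(v)
  n <- sum(valid)
  if (n == 0) stop("all risk cells are missing")
  need <- ceiling(100 / (100 - percentile))
  if (n < need)
    stop(sprintf("need at least %d valid cells for percentile %g (have %d)",
                 need, percentile, n))
  th <- as.numeric(stats::quantile(v[valid], percentile / 100, type = 7))
  mask <- valid & v >= th
  mask[!valid] <- NA
  new("HotspotMask", values = mask + 0, grid = risk@grid,
      name = paste0(risk@speciesId, "_hotspot"),
      percentile = percentile, threshold = th,
      nCells = as.integer(sum(mask, na.rm = TRUE)),
      speciesId = risk@speciesId)
}

#' Overlay per-species hotspot masks
#'
#' Per-cell count of species whose hotspot mask flags the cell, plus the
#' distribution of the hotspot-union cells over exact species counts k.
#'
#' @param masks list of [HotspotMask-class] on a shared grid, all at the
#'   same percentile.
#' @return an [OverlapMap-class].
#' @export
overlapHotspots <- function(masks) {
  if (!length(masks)) stop("no masks supplied")
  g <- masks[[1]]@grid; p <- masks[[1]]@percentile
  for (m in masks) {
    if (!gridsIdentical(m@grid, g)) stop("masks must share one grid")
    if (m@percentile != p)
      stop("masks must share one percentile (mixed percentiles supplied)")
  }
  counts <- Reduce(`+`, lapply(masks, function(m) {
    v <- m@values; v[is.na(v)] <- 0; v
  }))
  union <- counts >= 1
  kf <- if (any(union)) {
    tab <- tabulate(counts[union], nbins = length(masks))
    stats::setNames(tab / sum(union), seq_along(masks))
  } else stats::setNames(numeric(length(masks)), seq_along(masks))
  new("OverlapMap", values = counts, grid = g, name = "hotspot_overlap",
      percentile = p, kFractions = kf)
}

#' Tabulate multi-species overlap fractions
#'
#' Percentages (one decimal) of the hotspot-union cells flagged by exactly
#' k species, and the cumulative "more than k" aggregations.
#'
#' @param overlap an [OverlapMap-class].
#' @return list with data.frames `exact` (k, nCells, pct) and
#'   `greaterThan` (k, pct of union with count > k); both empty when the
#'   union is empty.
#' @export
overlapSummary <- function(overlap) {
  counts <- overlap@values
  union <- !is.na(counts) & counts >= 1
  nU <- sum(union)
  nSp <- length(overlap@kFractions)
  if (nU == 0)
    return(list(exact = data.frame(k = integer(), nCells = integer(),
                                   pct = numeric()),
                greaterThan = data.frame(k = integer(), pct = numeric())))
  tab <- tabulate(counts[union], nbins = nSp)
  exact <- data.frame(k = seq_len(nSp), nCells = tab,
                      pct = roundHalfUp(100 * tab / nU, 1))
  gt <- data.frame(k = seq_len(nSp - 1),
                   pct = roundHalfUp(
                     100 * rev(cumsum(rev(tab)))[-1] / nU, 1))
  list(exact = exact, greaterThan = gt)
}
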