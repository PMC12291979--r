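#' Spatially thin occurrence records to one per grid cell
#'
#' Retains at most one record per analysis-grid cell to reduce sampling
#' bias: the earliest-dated record in each cell, ties broken by input
#' order. Records falling outside the grid extent are dropped with a
#' warning. Thinning an already-thinned set returns it unchanged
#' (idempotent).
#'
#' @param occ an [OccurrenceSet-class].
#' @return a thinned [OccurrenceSet-class].
#' @export
thinOccurrences <- function(occ) {
  rec <- occ@records
  if (!nrow(rec)) {
    out <- occ; out@thinned <- TRUE; return(out)
  }
  idx <- cellIndexOf(occ@grid, rec$lon, rec$lat)
  outside <- is.na(idx$row)
  if (any(outside)) {
    warning(sum(outside), " record(s) outside the grid extent dropped")
    rec <- rec[!outside, , drop = FALSE]
    idx <- idx[!outside, , drop = FALSE]
  }
  cell <- (idx$col - 1L) * nRows(occ@grid) + idx$row
  ord <- order(rec$date, seq_len(nrow(rec)))
  keep <- ord[!duplicated(cell[ord])]
  rec <- rec[sort(keep), , drop = FALSE]
  rownames(rec) <- NULL
  new("OccurrenceSet", speciesId = occ@speciesId, records = rec,
      grid = occ@grid, thinned = TRUE)
}

#' Filter occurrences by range polygons
#'
#' Removes records outside all supplied range polygons (e.g. expert range
#' maps). An empty polygon list is an error, to distinguish "no range
#' filtering requested" (do not call this) from a degenerate range.
#'
#' @param occ an [OccurrenceSet-class].
#' @param rangePolygons non-empty list of two-column vertex matrices.
#' @return the filtered [OccurrenceSet-class]; a warning is raised when all
#'   records fall outside the range.
#' @export
filterByRange <- function(occ, rangePolygons) {
  if (!length(rangePolygons))
    stop("empty range polygon set; omit the range filter instead")
  rec <- occ@records
  if (!nrow(rec)) return(occ)
  keep <- rep(FALSE, nrow(rec))
  for (poly in rangePolygons)
    keep <- keep | pointInPolygon(rec$lon, rec$lat, poly)
  if (!any(keep))
    warning("all records fall outside the supplied range polygons")
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  new("OccurrenceSet", speciesId = occ@speciesId, records = rec,
      grid = occ@grid, thinned = occ@thinned)
}

#' Screen predictors for collinearity
#'
#' Greedy elimination on the Pearson correlation matrix (pairwise-complete
#' cells): while any pair exceeds `|r| > cutoff`, drop the variable with
#' the largest mean absolute correlation to the remaining variables. The
#' returned stack has no pair above the cutoff.
#'
#' @param env an [EnvStack-class] with at least two layers.
#' @param cutoff correlation magnitude above which a pair is collinear
#'   (default 0.7); must lie in (0, 1].
#' @return list with `env` (reduced [EnvStack-class]), `dropped` (character
#'   vector, in drop order) and `correlation` (the original matrix).
#' @export
selectVariables <- function(env, cutoff = 0.7) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (length(env@layers) < 2) stop("at least two predictors required")
  X <- vapply(env@layers, as.vector, numeric(length(env@layers[[1]])))
  r0 <- stats::cor(X, use = "pairwise.complete.obs")
  keep <- colnames(r0)
  r <- r0
  dropped <- character()
  repeat {
    a <- abs(r); diag(a) <- 0
    if (all(a <= cutoff, na.rm = TRUE) || length(keep) == 1) break
    meanAbs <- rowMeans(a, na.rm = TRUE)
    # only variables involved in a violating pair are candidates
    cand <- which(apply(a > cutoff, 1, any))
    worst <- cand[which.max(meanAbs[cand])]
    dropped <- c(dropped, keep[worst])
    keep <- keep[-worst]
    r <- r[keep, keep, drop = FALSE]
  }
  new("EnvStack", layers = env@layers[keep], grid = env@grid) |>
    (\(e) list(env = e, dropped = dropped, correlation = r0))()
}

#' Sample pseudo-absence background points
#'
#' Background cells are sampled uniformly at random, without replacement,
#' from sea cells (non-missing in the predictor stack) that hold no
#' presence record. The default background size equals the number of
#' presences (balanced classes).
#'
#' @param occ a (typically thinned) [OccurrenceSet-class].
#' @param env the [EnvStack-class] defining valid sea cells.
#' @param nPA number of background points; default the presence count.
#' @param seed integer seed.
#' @return data.frame with `lon`, `lat` at sampled cell centers.
#' @export
generatePseudoAbsences <- function(occ, env, nPA = nrow(occ@records),
                                   seed) {
  if (nPA < 1) stop("nPA must be at least 1")
  g <- env@grid
  ny <- nRows(g)
  sea <- !is.na(env@layers[[1]])
  idx <- cellIndexOf(g, occ@records$lon, occ@records$lat)
  presCell <- unique((idx$col - 1L) * ny + idx$row)
  candidates <- setdiff(which(sea), presCell)
  if (length(candidates) < nPA)
    stop(sprintf("only %d candidate cells for %d pseudo-absences",
                 length(candidates), nPA))
  withSeed(seed, {
    cells <- sample(candidates, nPA)
    row <- ((cells - 1L) %% ny) + 1L
    col <- ((cells - 1L) %/% ny) + 1L
    cc <- cellCenters(g)
    data.frame(lon = cc$lon[col], lat = cc$lat[row])
  })
}

#' Predictor values at point locations
#'
#' Looks up every layer of the stack at the cell containing each point.
#'
#' @param env an [EnvStack-class].
#' @param lon,lat coordinate vectors.
#' @return numeric matrix, one column per predictor.
#' @export
envValuesAt <- function(env, lon, lat) {
  idx <- cellIndexOf(env@grid, lon, lat)
  out <- vapply(env@layers, function(m) m[cbind(idx$row, idx$col)],
                numeric(length(lon)))
  if (length(lon) == 1) out <- matrix(out, nrow = 1,
                                      dimnames = list(NULL, names(env@layers)))
  out
}
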