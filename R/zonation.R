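#' Shipping pressure at a point site
#'
#' The maximum vessel-hours over the eight grid cells closest to the point:
#' the Moore neighborhood of the cell containing it. At grid corners and
#' edges the neighborhood is clipped to existing cells; missing cells are
#' ignored. When every candidate cell is missing (or the point falls
#' outside the grid) the site cannot be assessed and `NA` is returned with
#' a reason attribute, to be excluded upstream.
#'
#' @param lon,lat point coordinates.
#' @param traffic a [TrafficGrid-class].
#' @param includeCenter also consider the containing cell itself (default
#'   FALSE: the eight surrounding cells only).
#' @return vessel-hours value, or `NA` with attribute `reason` when the
#'   site must be excluded.
#' @export
assignPointPressure <- function(lon, lat, traffic, includeCenter = FALSE) {
  g <- traffic@grid
  idx <- cellIndexOf(g, lon, lat)
  if (is.na(idx$row)) {
    return(structure(NA_real_, reason = "outside_extent"))
  }
  ny <- nRows(g); nx <- nCols(g)
  rows <- idx$row + (-1):1
  cols <- idx$col + (-1):1
  cand <- expand.grid(row = rows, col = cols)
  if (!includeCenter)
    cand <- cand[!(cand$row == idx$row & cand$col == idx$col), ]
  cand <- cand[cand$row >= 1 & cand$row <= ny &
               cand$col >= 1 & cand$col <= nx, ]
  vals <- traffic@values[cbind(cand$row, cand$col)]
  if (all(is.na(vals)))
    return(structure(NA_real_, reason = "no_traffic_coverage"))
  max(vals, na.rm = TRUE)
}

#' Shipping pressure over a polygon site
#'
#' The unweighted mean of vessel-hours over all non-missing cells whose
#' centers fall inside the polygon (boundary inclusive). A polygon whose
#' bounding box spans less than one fine cell (0.1 degree) in both axes is
#' simplified to its centroid and handled as a point. A polygon covering no
#' non-missing cell centers cannot be assessed and returns `NA` with a
#' reason attribute.
#'
#' @param poly two-column vertex matrix.
#' @param traffic a [TrafficGrid-class].
#' @param simplifySpan bounding-box span (degrees) below which the polygon
#'   is treated as a point; defaults to the traffic grid resolution.
#' @return vessel-hours value, or `NA` with attribute `reason`.
#' @export
assignPolygonPressure <- function(poly, traffic,
                                  simplifySpan = traffic@grid@res) {
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3 ||
      any(!is.finite(poly)))
    stop("invalid polygon geometry")
  span <- bboxSpan(poly)
  if (span["lon"] < simplifySpan && span["lat"] < simplifySpan) {
    ctr <- polygonCentroid(poly)
    return(assignPointPressure(ctr[1], ctr[2], traffic))
  }
  g <- traffic@grid
  cc <- cellCenters(g)
  # candidate cells limited to the polygon's bounding box
  cols <- which(cc$lon >= min(poly[, 1]) - g@res &
                cc$lon <= max(poly[, 1]) + g@res)
  rows <- which(cc$lat >= min(poly[, 2]) - g@res &
                cc$lat <= max(poly[, 2]) + g@res)
  if (!length(cols) || !length(rows))
    return(structure(NA_real_, reason = "no_cells_covered"))
  cand <- expand.grid(row = rows, col = cols)
  inside <- pointInPolygon(cc$lon[cand$col], cc$lat[cand$row], poly)
  vals <- traffic@values[cbind(cand$row, cand$col)][inside]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    return(structure(NA_real_, reason = "no_cells_covered"))
  mean(vals)
}

#' Classify the jurisdiction of protected sites
#'
#' A site whose geometry intersects (or touches) any high-seas polygon is
#' transboundary; a site fully within EEZ waters is national. MPAs are
#' always national: marine protected areas are assumed absent from the
#' high seas.
#'
#' @param sites a [SiteSet-class].
#' @param highSeas list of high-seas boundary polygons (two-column
#'   matrices).
#' @return the SiteSet with a filled `jurisdiction` column.
#' @export
classifyJurisdiction <- function(sites, highSeas) {
  tab <- sites@table
  n <- nrow(tab)
  jur <- character(n)
  for (i in seq_len(n)) {
    if (tab$category[i] == "MPA") { jur[i] <- "national"; next }
    geom <- sites@geometry[[i]]
    hit <- FALSE
    for (hs in highSeas) {
      hit <- if (is.matrix(geom)) polygonsIntersect(geom, hs)
             else pointInPolygon(geom[1], geom[2], hs)
      if (hit) break
    }
    jur[i] <- if (hit) "transboundary" else "national"
  }
  tab$jurisdiction <- jur
  new("SiteSet", table = tab, geometry = sites@geometry)
}

#' Assign shipping pressure, level and stress to every site
#'
#' Runs point/polygon pressure assignment over a site collection, derives
#' the intensity level and stress class from the assigned vessel-hours,
#' computes geodesic site areas, and records exclusions (sites outside the
#' grid or without traffic coverage) with reason codes instead of dropping
#' them silently.
#'
#' @param sites a [SiteSet-class].
#' @param traffic a [TrafficGrid-class].
#' @param includeCenter passed to [assignPointPressure()].
#' @return the SiteSet with `pressure_hours`, `level`, `stress`,
#'   `area_km2`, `excluded`, `exclude_reason` columns filled.
#' @export
assignSitePressure <- function(sites, traffic, includeCenter = FALSE) {
  tab <- sites@table
  n <- nrow(tab)
  ph <- rep(NA_real_, n); reason <- rep(NA_character_, n)
  area <- numeric(n)
  for (i in seq_len(n)) {
    geom <- sites@geometry[[i]]
    v <- if (is.matrix(geom))
      assignPolygonPressure(geom, traffic)
    else
      assignPointPressure(geom[1], geom[2], traffic,
                          includeCenter = includeCenter)
    ph[i] <- as.numeric(v)
    if (is.na(ph[i])) reason[i] <- attr(v, "reason")
    area[i] <- geodesicAreaKm2(geom)
  }
  tab$pressure_hours <- ph
  tab$excluded <- is.na(ph)
  tab$exclude_reason <- reason
  tab$level <- as.integer(intensityLevel(ph))
  tab$stress <- NA_character_
  ok <- !is.na(tab$level)
  if (any(ok)) tab$stress[ok] <- stressClass(tab$level[ok])
  tab$area_km2 <- area
  new("SiteSet", table = tab, geometry = sites@geometry)
}

#' Summarize shipping pressure over protected sites
#'
#' Per-category counts and count shares by intensity level, and counts,
#' count shares and geodesic-area shares by stress class. Shares are
#' percentages of the category's valid (non-excluded) sites, rounded half
#' away from zero to two decimals, matching printed report precision.
#' Excluded sites are tallied separately, never silently dropped.
#'
#' @param sites a [SiteSet-class] with pressure assigned (see
#'   [assignSitePressure()]), or a data.frame with at least `category` and
#'   `level` columns (and optionally `stress`, `area_km2`, `excluded`) for
#'   summarizing externally reported count tables.
#' @return list with `byLevel` (category, level, n, pct), `byStress`
#'   (category, stress, n, pct, pctArea) data.frames and `nExcluded`.
#' @examples
#' # a printed count table can be summarized directly:
#' tab <- data.frame(category = "EBSA",
#'                   level = rep(1:6, c(2, 61, 109, 96, 46, 5)))
#' summarizePressure(tab)$byLevel$pct
#' @export
summarizePressure <- function(sites) {
  tab <- if (is(sites, "SiteSet")) sites@table else as.data.frame(sites)
  if (!nrow(tab))
    return(list(byLevel = data.frame(category = character(),
                                     level = integer(), n = integer(),
                                     pct = numeric()),
                byStress = data.frame(category = character(),
                                      stress = character(), n = integer(),
                                      pct = numeric(), pctArea = numeric()),
                nExcluded = 0L))
  if (!"excluded" %in% names(tab)) tab$excluded <- is.na(tab$level)
  nExcluded <- sum(tab$excluded)
  tab <- tab[!tab$excluded, , drop = FALSE]
  if (!"stress" %in% names(tab)) tab$stress <- stressClass(tab$level)
  if (!"area_km2" %in% names(tab)) tab$area_km2 <- NA_real_
  byLevel <- do.call(rbind, lapply(split(tab, tab$category), function(d) {
    agg <- as.data.frame(table(level = d$level), stringsAsFactors = FALSE)
    data.frame(category = d$category[1],
               level = as.integer(agg$level), n = as.integer(agg$Freq),
               pct = roundHalfUp(100 * agg$Freq / nrow(d), 2))
  }))
  stressLevels <- c("low", "moderate", "high")
  byStress <- do.call(rbind, lapply(split(tab, tab$category), function(d) {
    n <- vapply(stressLevels, function(s) sum(d$stress == s), integer(1))
    a <- vapply(stressLevels, function(s)
      sum(d$area_km2[d$stress == s], na.rm = TRUE), numeric(1))
    totA <- sum(d$area_km2, na.rm = TRUE)
    data.frame(category = d$category[1], stress = stressLevels,
               n = n, pct = roundHalfUp(100 * n / nrow(d), 2),
               pctArea = if (totA > 0) roundHalfUp(100 * a / totA, 2)
                         else NA_real_)
  }))
  rownames(byLevel) <- rownames(byStress) <- NULL
  list(byLevel = byLevel, byStress = byStress, nExcluded = nExcluded)
}

#' Share of sites in a jurisdiction class
#'
#' Convenience count share (percent, two decimals): e.g. the fraction of a
#' category's sites classified transboundary (high seas).
#'
#' @param sites a [SiteSet-class] with `jurisdiction` filled, or a
#'   data.frame with `category` and `jurisdiction`.
#' @param category site category to summarize.
#' @param jurisdiction class of interest.
#' @export
jurisdictionShare <- function(sites, category = "IMMA",
                              jurisdiction = "transboundary") {
  tab <- if (is(sites, "SiteSet")) sites@table else as.data.frame(sites)
  tab <- tab[tab$category == category, , drop = FALSE]
  if (!nrow(tab)) return(NA_real_)
  roundHalfUp(100 * sum(tab$jurisdiction == jurisdiction) / nrow(tab), 2)
}
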