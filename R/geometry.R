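# Planar lon/lat geometry predicates. Polygons are two-column matrices of
# vertices (lon, lat), not closed; cells and polygons are assumed not to
# cross the antimeridian (antimeridian-crossing geometries must be
# pre-split by the caller).

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray casting with an explicit on-boundary check: points lying
#' exactly on a polygon edge or vertex count as inside. The inclusive rule
#' matters for jurisdiction classification, where a site touching the
#' high-seas boundary is transboundary.
#'
#' @param lon,lat point coordinate vectors.
#' @param poly two-column vertex matrix.
#' @return logical vector.
#' @export
pointInPolygon <- function(lon, lat, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  px <- poly[, 1]; py <- poly[, 2]
  nv <- length(px)
  jx <- px[c(nv, seq_len(nv - 1L))]; jy <- py[c(nv, seq_len(nv - 1L))]
  inside <- rep(FALSE, n)
  onEdge <- rep(FALSE, n)
  eps <- 1e-12
  for (e in seq_len(nv)) {
    x1 <- jx[e]; y1 <- jy[e]; x2 <- px[e]; y2 <- py[e]
    # boundary: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    onSeg <- abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      lon >= pmin(x1, x2) - eps & lon <= pmax(x1, x2) + eps &
      lat >= pmin(y1, y2) - eps & lat <= pmax(y1, y2) + eps
    onEdge <- onEdge | onSeg
    hits <- ((y1 > lat) != (y2 > lat)) &
      (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
    hits[is.na(hits)] <- FALSE
    inside <- xor(inside, hits)
  }
  inside | onEdge
}

# Do segments p1-p2 and p3-p4 intersect (touching counts)?
segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  onSeg <- function(a, b, c) {
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
      min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (abs(d1) < 1e-12 && onSeg(p3, p4, p1)) ||
    (abs(d2) < 1e-12 && onSeg(p3, p4, p2)) ||
    (abs(d3) < 1e-12 && onSeg(p1, p2, p3)) ||
    (abs(d4) < 1e-12 && onSeg(p1, p2, p4))
}

#' Do two polygons intersect?
#'
#' True when any vertex of one lies inside (or on) the other, or any pair
#' of edges crosses. Sufficient for simple (non-self-intersecting)
#' polygons.
#'
#' @param a,b two-column vertex matrices.
#' @export
polygonsIntersect <- function(a, b) {
  if (any(pointInPolygon(a[, 1], a[, 2], b))) return(TRUE)
  if (any(pointInPolygon(b[, 1], b[, 2], a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[if (i == na) 1L else i + 1L, ]
    for (j in seq_len(nb)) {
      p3 <- b[j, ]; p4 <- b[if (j == nb) 1L else j + 1L, ]
      if (segmentsIntersect(p1, p2, p3, p4)) return(TRUE)
    }
  }
  FALSE
}

# Longitude/latitude spans of a geometry's bounding box.
bboxSpan <- function(geom) {
  if (is.matrix(geom))
    c(lon = diff(range(geom[, 1])), lat = diff(range(geom[, 2])))
  else c(lon = 0, lat = 0)
}

# Vertex-average centroid; adequate for the small, simple site polygons
# handled here (used only to pick a representative cell).
polygonCentroid <- function(poly) {
  c(mean(poly[, 1]), mean(poly[, 2]))
}

#' Geodesic area of a site geometry in square kilometres
#'
#' Computed on the WGS84 ellipsoid; point geometries have area 0.
#'
#' @param geom a point (`c(lon, lat)`) or polygon vertex matrix.
#' @export
geodesicAreaKm2 <- function(geom) {
  if (!is.matrix(geom)) return(0)
  abs(geosphere::areaPolygon(geom)) / 1e6
}
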