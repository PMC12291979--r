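#' @import methods
NULL

#' Regular longitude-latitude grid descriptor
#'
#' Describes a regular grid of square (in degrees) cells covering
#' `[xmin, xmax) x [ymin, ymax)`. Cells are half-open in both axes: a point
#' on a cell's west or south edge belongs to that cell. Raster values are
#' stored as matrices with row 1 = the southernmost latitude band and
#' column 1 = the westernmost longitude band.
#'
#' @slot xmin,xmax,ymin,ymax numeric extent in decimal degrees, longitude in
#'   `[-180, 180)`.
#' @slot res numeric cell size in degrees (same in both axes).
#' @export
setClass("GridSpec",
  representation(xmin = "numeric", xmax = "numeric",
                 ymin = "numeric", ymax = "numeric", res = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@res <= 0) msg <- c(msg, "res must be positive")
    if (object@xmax <= object@xmin) msg <- c(msg, "xmax must exceed xmin")
    if (object@ymax <= object@ymin) msg <- c(msg, "ymax must exceed ymin")
    nx <- (object@xmax - object@xmin) / object@res
    ny <- (object@ymax - object@ymin) / object@res
    if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
      msg <- c(msg, "extent must be an integer number of cells")
    if (is.null(msg)) TRUE else msg
  })

#' A single raster layer on a grid
#'
#' @slot values numeric matrix, `nRows(grid)` by `nCols(grid)`; `NA` marks
#'   missing (e.g. land) cells, distinct from zero.
#' @slot grid a [GridSpec-class].
#' @slot name layer name.
#' @export
setClass("GridLayer",
  representation(values = "matrix", grid = "GridSpec", name = "character"),
  prototype(name = ""),
  validity = function(object) {
    g <- object@grid
    ny <- round((g@ymax - g@ymin) / g@res)
    nx <- round((g@xmax - g@xmin) / g@res)
    if (nrow(object@values) != ny || ncol(object@values) != nx)
      return(sprintf("values must be %d x %d to match grid", ny, nx))
    TRUE
  })

#' Vessel-activity hours per grid cell
#'
#' Raw shipping-pressure signal: nonnegative vessel-hours on the fine
#' analysis grid. `NA` cells are outside traffic coverage and are kept
#' distinct from true zero-traffic cells.
#'
#' @slot laneMask logical matrix marking constructed shipping-corridor
#'   cells; filled by the synthetic generator (provenance for recovery
#'   experiments), empty (0 x 0) for observed traffic.
#' @export
setClass("TrafficGrid", contains = "GridLayer",
  representation(laneMask = "matrix"),
  prototype(laneMask = matrix(logical(0), 0, 0)),
  validity = function(object) {
    v <- object@values
    if (any(v[!is.na(v)] < 0)) return("vessel hours must be nonnegative")
    TRUE
  })

#' Discrete shipping-intensity levels
#'
#' Integer levels 0-7: level 0 for sub-unit traffic (hours < 1), levels 1-7
#' decade bins of vessel-hours capped at 7. Levels 1-3 are "low", 4
#' "moderate", 5-7 "high" shipping stress.
#' @export
setClass("IntensityGrid", contains = "GridLayer",
  validity = function(object) {
    v <- object@values[!is.na(object@values)]
    if (length(v) && (any(v < 0) || any(v > 7) || any(v != round(v))))
      return("levels must be integers in 0..7")
    TRUE
  })

#' Normalized shipping density index Vi
#'
#' Log10-transformed vessel-hours clamped at `floorHours`, rescaled to
#' `[0, 1]` so the global maximum-hours cell scores 1 and any cell at or
#' below the floor scores 0.
#'
#' @slot floorHours the clamp threshold in vessel-hours (default 10).
#' @slot maxLog `log10` of the global maximum hours, the normalization
#'   constant.
#' @export
setClass("DensityIndex", contains = "GridLayer",
  representation(floorHours = "numeric", maxLog = "numeric"))

#' Stack of environmental predictor rasters
#'
#' Named predictor layers sharing one grid (e.g. SST, Sal, Chl, MLD, SIT,
#' SSH, SIC, Bat, TS, TA, DS). All layers share the same missing-cell
#' (land) pattern.
#'
#' @slot layers named list of numeric matrices.
#' @slot grid shared [GridSpec-class].
#' @export
setClass("EnvStack",
  representation(layers = "list", grid = "GridSpec"),
  validity = function(object) {
    if (length(object@layers) < 1) return("at least one layer required")
    if (is.null(names(object@layers)) || any(names(object@layers) == ""))
      return("layers must be named")
    if (anyDuplicated(names(object@layers)))
      return("layer names must be unique")
    g <- object@grid
    ny <- round((g@ymax - g@ymin) / g@res)
    nx <- round((g@xmax - g@xmin) / g@res)
    ok <- vapply(object@layers, function(m)
      is.matrix(m) && nrow(m) == ny && ncol(m) == nx, logical(1))
    if (!all(ok)) return("all layers must be matrices matching the grid")
    TRUE
  })

#' Species occurrence records on an analysis grid
#'
#' @slot speciesId species label.
#' @slot records data.frame with columns `lon`, `lat`, `date` (class `Date`).
#' @slot grid the coarse analysis grid the records are referenced to.
#' @slot thinned logical: has one-per-cell spatial thinning been applied.
#' @export
setClass("OccurrenceSet",
  representation(speciesId = "character", records = "data.frame",
                 grid = "GridSpec", thinned = "logical"),
  prototype(thinned = FALSE),
  validity = function(object) {
    need <- c("lon", "lat", "date")
    if (!all(need %in% names(object@records)))
      return("records must have columns lon, lat, date")
    TRUE
  })

#' Ground-truth habitat suitability for a synthetic species
#'
#' The inverse-logit of a linear combination of standardized predictors;
#' used to generate occurrences and to score how well the ensemble recovers
#' a known surface.
#'
#' @slot speciesId species label.
#' @slot coefficients named per-variable response weights.
#' @slot surface a [GridLayer-class] with values in `[0, 1]`.
#' @export
setClass("TrueSuitability",
  representation(speciesId = "character", coefficients = "numeric",
                 surface = "GridLayer"))

#' Continuous habitat-suitability map Di from a weighted ensemble
#'
#' @slot speciesId species label.
#' @slot di suitability raster in `[0, 1]` (a [GridLayer-class]).
#' @slot weights named nonnegative per-learner ensemble weights summing
#'   to 1; only learners passing the AUC cutoff carry weight.
#' @slot threshold binarization cutoff (`NA` until [binarize()] is called).
#' @export
setClass("SuitabilityMap",
  representation(speciesId = "character", di = "GridLayer",
                 weights = "numeric", threshold = "numeric"),
  prototype(threshold = NA_real_),
  validity = function(object) {
    v <- object@di@values
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      return("di must lie in [0, 1]")
    if (length(object@weights)) {
      if (any(object@weights < 0)) return("weights must be nonnegative")
      if (abs(sum(object@weights) - 1) > 1e-8)
        return("weights must sum to 1")
    }
    TRUE
  })

#' Species richness raster: per-cell count of stacked binary maps
#' @export
setClass("RichnessMap", contains = "GridLayer",
  representation(nSpecies = "integer"))

#' Collision-risk map Ri = Vi x Di
#'
#' @slot speciesId species label.
#' @slot provenance identifiers of the Vi and Di inputs.
#' @export
setClass("RiskMap", contains = "GridLayer",
  representation(speciesId = "character", provenance = "character"))

#' Percentile hotspot mask of a risk map
#'
#' @slot percentile the percentile used (e.g. 99 for "top 1% risk").
#' @slot threshold the risk value at that percentile.
#' @slot nCells number of flagged cells.
#' @slot speciesId species label.
#' @export
setClass("HotspotMask", contains = "GridLayer",
  representation(percentile = "numeric", threshold = "numeric",
                 nCells = "integer", speciesId = "character"))

#' Multi-species hotspot overlap counts
#'
#' @slot percentile the percentile shared by the stacked masks.
#' @slot kFractions named numeric: fraction of the hotspot-union cells
#'   flagged by exactly k species, k = 1..n.
#' @export
setClass("OverlapMap", contains = "GridLayer",
  representation(percentile = "numeric", kFractions = "numeric"))

#' Collection of protected sites (MPA / EBSA / IMMA)
#'
#' Tabular site attributes plus a parallel list of geometries. Geometries
#' are either a length-2 numeric `c(lon, lat)` (point sites) or a two-column
#' matrix of polygon vertices in counter-clockwise order, not closed.
#'
#' @slot table data.frame with columns `site_id`, `category`, `geom_type`,
#'   and after pressure assignment `pressure_hours`, `level`, `stress`,
#'   `jurisdiction`, `area_km2`, `excluded`, `exclude_reason`.
#' @slot geometry list of site geometries, parallel to `table` rows.
#' @export
setClass("SiteSet",
  representation(table = "data.frame", geometry = "list"),
  validity = function(object) {
    if (nrow(object@table) != length(object@geometry))
      return("one geometry per table row required")
    need <- c("site_id", "category", "geom_type")
    if (nrow(object@table) && !all(need %in% names(object@table)))
      return("table must have site_id, category, geom_type")
    if (nrow(object@table) &&
        !all(object@table$category %in% c("MPA", "EBSA", "IMMA")))
      return("category must be MPA, EBSA or IMMA")
    TRUE
  })

#' A self-contained synthetic study region
#'
#' Fine (traffic) and coarse (predictor) grids over the same extent, a
#' procedurally drawn single-landmass coastline aligned to both grids, and
#' a high-seas boundary geometry. The seed fully determines every
#' downstream draw made from the world.
#'
#' @slot gridFine 0.1-degree class analysis grid for traffic.
#' @slot gridCoarse 0.25-degree class grid for predictors and suitability.
#' @slot landFine,landCoarse logical land masks on each grid (TRUE = land).
#' @slot highSeas list of polygons (two-column lon/lat matrices) delimiting
#'   waters beyond national jurisdiction.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticWorld",
  representation(gridFine = "GridSpec", gridCoarse = "GridSpec",
                 landFine = "matrix", landCoarse = "matrix",
                 highSeas = "list", seed = "integer"),
  validity = function(object) {
    f <- object@gridFine; c <- object@gridCoarse
    if (f@xmin != c@xmin || f@xmax != c@xmax ||
        f@ymin != c@ymin || f@ymax != c@ymax)
      return("fine and coarse grids must cover identical extents")
    if (f@res >= c@res) return("fine resolution must be finer than coarse")
    TRUE
  })

#' Learner/evaluation record from repeated cross-validation
#'
#' @slot learnerId label of the learner evaluated.
#' @slot auc mean held-out AUC over all folds.
#' @slot tss mean held-out TSS (at the TSS-maximizing threshold per fold).
#' @slot folds,repeats cross-validation layout; `folds * repeats`
#'   evaluations were averaged.
#' @export
setClass("EvaluationRecord",
  representation(learnerId = "character", auc = "numeric", tss = "numeric",
                 folds = "integer", repeats = "integer"),
  validity = function(object) {
    if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
    if (object@tss < -1 || object@tss > 1) return("tss must be in [-1, 1]")
    TRUE
  })
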