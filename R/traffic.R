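#' Construct a traffic grid from an hours matrix
#'
#' @param hours nonnegative numeric matrix of vessel-hours (`NA` = no
#'   coverage).
#' @param grid matching [GridSpec-class].
#' @return a [TrafficGrid-class].
#' @export
trafficGrid <- function(hours, grid) {
  if (any(hours[!is.na(hours)] < 0))
    stop("vessel hours must be nonnegative")
  new("TrafficGrid", values = hours, grid = grid, name = "vessel_hours")
}

#' Classify vessel-hours into discrete shipping-intensity levels
#'
#' Decade (log10) bins: level 0 for sub-unit traffic (`hours < 1`), then
#' `level = min(7, 1 + floor(log10(hours)))`, so level 1 covers `[1, 10)`
#' hours, level 2 `[10, 100)`, and so on, capped at level 7. Missing cells
#' stay missing. The level is monotone in hours.
#'
#' @param traffic a [TrafficGrid-class].
#' @return an [IntensityGrid-class].
#' @examples
#' g <- gridSpec4326(0, 1, 0, 1, 0.5)
#' tr <- trafficGrid(matrix(c(0, 5, 999, 1e8), 2, 2), g)
#' gridValues(classifyIntensity(tr))
#' @export
classifyIntensity <- function(traffic) {
  h <- traffic@values
  lev <- intensityLevel(h)
  attributes(lev) <- attributes(h)
  new("IntensityGrid", values = lev, grid = traffic@grid,
      name = "intensity_level")
}

#' Intensity level of a vessel-hours value
#'
#' Scalar/vector form of the decade-bin rule used by [classifyIntensity()]:
#' 0 below one hour, otherwise `min(7, 1 + floor(log10(h)))`.
#'
#' @param hours nonnegative vessel-hours (vector or matrix); `NA` passes
#'   through.
#' @export
intensityLevel <- function(hours) {
  if (any(hours[!is.na(hours)] < 0)) stop("vessel hours must be nonnegative")
  ifelse(hours < 1, 0, pmin(7, 1 + floor(log10(hours))))
}

#' Shipping stress class of an intensity level
#'
#' Levels 1-3 are low, level 4 moderate, levels 5-7 high shipping stress;
#' level 0 (sub-unit traffic) is folded into "low".
#'
#' @param level integer vector of levels in 0..7.
#' @return character vector in `c("low", "moderate", "high")`.
#' @export
stressClass <- function(level) {
  if (any(is.na(level)) || any(level < 0 | level > 7 | level != round(level)))
    stop("level must be an integer in 0..7")
  cut(level, breaks = c(-1, 3, 4, 7),
      labels = c("low", "moderate", "high")) |> as.character()
}

#' Compute the normalized shipping density index Vi
#'
#' Log-transform with a minimum threshold followed by 0-1 normalization:
#' hours are clamped below at `floorHours`, log10-transformed, and rescaled
#' so a cell at or below the floor scores 0 and the global maximum-hours
#' cell scores 1:
#' `vi = (log10(max(h, floor)) - log10(floor)) / (log10(hmax) - log10(floor))`.
#'
#' @param traffic a [TrafficGrid-class].
#' @param floorHours the clamp threshold (default 10 vessel-hours).
#' @return a [DensityIndex-class]. Missing cells propagate as missing.
#' @export
computeDensityIndex <- function(traffic, floorHours = 10) {
  if (floorHours <= 0) stop("floorHours must be positive")
  h <- traffic@values
  hmax <- suppressWarnings(max(h, na.rm = TRUE))
  if (!is.finite(hmax) || hmax <= floorHours)
    stop("normalization undefined: no cell exceeds the floor of ",
         floorHours, " hours")
  lf <- log10(floorHours)
  vi <- (log10(pmax(h, floorHours)) - lf) / (log10(hmax) - lf)
  new("DensityIndex", values = vi, grid = traffic@grid,
      name = "shipping_density_vi", floorHours = floorHours,
      maxLog = log10(hmax))
}
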