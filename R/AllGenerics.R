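#' Extract the raster values of an object
#' @param x an object holding a raster.
#' @return a numeric matrix (row 1 = southernmost band).
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' Extract the grid descriptor of an object
#' @param x an object referenced to a grid.
#' @return a [GridSpec-class].
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' Species label of an object
#' @param x an object carrying a species identifier.
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "GridLayer", function(x) x@values)
#' @rdname gridValues
#' @export
setMethod("gridValues", "SuitabilityMap", function(x) x@di@values)
#' @rdname gridValues
#' @export
setMethod("gridValues", "TrueSuitability", function(x) x@surface@values)

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "GridLayer", function(x) x@grid)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "EnvStack", function(x) x@grid)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "SuitabilityMap", function(x) x@di@grid)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "OccurrenceSet", function(x) x@grid)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "TrueSuitability", function(x) x@surface@grid)

#' @rdname speciesId
#' @export
setMethod("speciesId", "OccurrenceSet", function(x) x@speciesId)
#' @rdname speciesId
#' @export
setMethod("speciesId", "SuitabilityMap", function(x) x@speciesId)
#' @rdname speciesId
#' @export
setMethod("speciesId", "TrueSuitability", function(x) x@speciesId)
#' @rdname speciesId
#' @export
setMethod("speciesId", "RiskMap", function(x) x@speciesId)

#' Number of grid columns (longitude bands)
#' @param x a [GridSpec-class].
#' @export
nCols <- function(x) as.integer(round((x@xmax - x@xmin) / x@res))

#' Number of grid rows (latitude bands)
#' @param x a [GridSpec-class].
#' @export
nRows <- function(x) as.integer(round((x@ymax - x@ymin) / x@res))

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g deg, lon [%g, %g) lat [%g, %g)\n",
              nRows(object), nCols(object), object@res,
              object@xmin, object@xmax, object@ymin, object@ymax))
})

setMethod("show", "GridLayer", function(object) {
  v <- object@values
  cat(sprintf("%s '%s': %d x %d cells, %d missing, range [%g, %g]\n",
              class(object), object@name, nrow(v), ncol(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  show(object@grid)
})

setMethod("show", "EnvStack", function(object) {
  cat(sprintf("EnvStack with %d predictors: %s\n",
              length(object@layers),
              paste(names(object@layers), collapse = ", ")))
  show(object@grid)
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet '%s': %d records%s\n", object@speciesId,
              nrow(object@records),
              if (isTRUE(object@thinned)) " (thinned)" else ""))
})

setMethod("show", "SuitabilityMap", function(object) {
  cat(sprintf("SuitabilityMap '%s': ensemble of %d learner(s)%s\n",
              object@speciesId, length(object@weights),
              if (is.na(object@threshold)) ""
              else sprintf(", threshold %.4f", object@threshold)))
  show(object@di)
})

setMethod("show", "SiteSet", function(object) {
  tab <- table(factor(object@table$category,
                      levels = c("MPA", "EBSA", "IMMA")))
  cat(sprintf("SiteSet: %d sites (MPA %d, EBSA %d, IMMA %d)\n",
              nrow(object@table), tab["MPA"], tab["EBSA"], tab["IMMA"]))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf("SyntheticWorld (seed %d): %.0f%% land\n", object@seed,
              100 * mean(object@landCoarse)))
  show(object@gridFine)
  show(object@gridCoarse)
})

setMethod("show", "EvaluationRecord", function(object) {
  cat(sprintf("EvaluationRecord '%s': AUC %.4f, TSS %.4f (%d x %d folds)\n",
              object@learnerId, object@auc, object@tss,
              object@folds, object@repeats))
})

setMethod("show", "HotspotMask", function(object) {
  cat(sprintf("HotspotMask '%s' at percentile %g: %d cells >= %.6g\n",
              object@speciesId, object@percentile, object@nCells,
              object@threshold))
})
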