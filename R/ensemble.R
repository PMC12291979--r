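#' Fitted ensemble with its calibration data
#'
#' Returned by [fitSuitability()]; bundles the suitability map with the
#' learners, fitted models, evaluation records and calibration design
#' matrix needed for binarization and permutation importance.
#'
#' @slot map the weighted-ensemble [SuitabilityMap-class].
#' @slot evals list of [EvaluationRecord-class], one per learner.
#' @slot learners,models parallel lists of learner objects and their
#'   full-data fits.
#' @slot calibX calibration predictor matrix (presences then absences).
#' @slot calibY logical calibration response.
#' @slot env the reduced [EnvStack-class] used for modeling.
#' @export
setClass("EnsembleFit",
  representation(map = "SuitabilityMap", evals = "list",
                 learners = "list", models = "list",
                 calibX = "matrix", calibY = "logical",
                 env = "EnvStack"))

setMethod("show", "EnsembleFit", function(object) {
  cat(sprintf("EnsembleFit '%s' (%d learner(s) kept of %d)\n",
              object@map@speciesId, length(object@map@weights),
              length(object@learners)))
  for (ev in object@evals) show(ev)
})

#' Combine learner projections into a weighted-ensemble suitability map
#'
#' Only high-performance learners enter the ensemble: those with mean
#' held-out AUC above `aucCutoff` (default 0.9). Weights are proportional
#' to AUC among the kept learners and sum to 1, so the ensemble stays in
#' `[0, 1]`.
#'
#' @param projections named list of score matrices, one per learner.
#' @param evals list of [EvaluationRecord-class] parallel to
#'   `projections`.
#' @param grid shared [GridSpec-class].
#' @param aucCutoff AUC admission threshold.
#' @param speciesId species label.
#' @return a [SuitabilityMap-class].
#' @export
buildEnsemble <- function(projections, evals, grid, aucCutoff = 0.9,
                          speciesId = "species") {
  if (length(projections) != length(evals))
    stop("one evaluation record per projection required")
  aucs <- vapply(evals, function(e) e@auc, numeric(1))
  ids <- vapply(evals, function(e) e@learnerId, character(1))
  keep <- which(aucs > aucCutoff)
  if (!length(keep))
    stop(sprintf(paste0(
      "no learner exceeds the AUC cutoff of %.2f (best: %.3f); ",
      "consider relaxing aucCutoff"), aucCutoff, max(aucs)))
  w <- aucs[keep] / sum(aucs[keep])
  names(w) <- ids[keep]
  di <- Reduce(`+`, Map(function(p, wi) p * wi, projections[keep], w))
  di <- pmin(pmax(di, 0), 1)
  new("SuitabilityMap", speciesId = speciesId,
      di = new("GridLayer", values = di, grid = grid, name = "di"),
      weights = w, threshold = NA_real_)
}

#' Fit the full ensemble habitat-suitability model for one species
#'
#' End-to-end species workflow: spatial thinning, pseudo-absence sampling,
#' repeated stratified cross-validation of each learner, full-data refits,
#' raster projection, and AUC-weighted ensembling of the learners passing
#' the AUC cutoff.
#'
#' @param occ an [OccurrenceSet-class] (thinned automatically if needed).
#' @param env a (collinearity-screened) [EnvStack-class].
#' @param learners list of learner objects; defaults to the two reference
#'   learners.
#' @param nPA pseudo-absence count; default equals the thinned presence
#'   count.
#' @param k,repeats cross-validation layout (default 5 x 10).
#' @param aucCutoff ensemble admission threshold (default 0.9).
#' @param seed integer seed driving pseudo-absences and fold splits.
#' @return an [EnsembleFit-class].
#' @export
fitSuitability <- function(occ, env,
                           learners = list(makeLogisticLearner(),
                                           makeNearestEnvLearner()),
                           nPA = NULL, k = 5, repeats = 10,
                           aucCutoff = 0.9, seed) {
  if (!isTRUE(occ@thinned)) occ <- thinOccurrences(occ)
  if (is.null(nPA)) nPA <- nrow(occ@records)
  pa <- generatePseudoAbsences(occ, env, nPA, seed = childSeed(seed, "pa"))
  Xp <- envValuesAt(env, occ@records$lon, occ@records$lat)
  Xa <- envValuesAt(env, pa$lon, pa$lat)
  X <- rbind(Xp, Xa)
  y <- c(rep(TRUE, nrow(Xp)), rep(FALSE, nrow(Xa)))
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  evals <- list(); models <- list(); projections <- list()
  for (i in seq_along(learners)) {
    L <- learners[[i]]
    evals[[i]] <- crossValidate(L, X, y, k = k, repeats = repeats,
                                seed = childSeed(seed, paste0("cv", L$id)))
    models[[i]] <- withSeed(childSeed(seed, paste0("fit", L$id)),
                            L$fit(X, y))
    projections[[i]] <- projectLearner(L, models[[i]], env)
  }
  names(projections) <- vapply(learners, `[[`, character(1), "id")
  map <- buildEnsemble(projections, evals, env@grid,
                       aucCutoff = aucCutoff, speciesId = occ@speciesId)
  new("EnsembleFit", map = map, evals = evals, learners = learners,
      models = models, calibX = X, calibY = y, env = env)
}

#' Binarize a suitability map at the TSS-maximizing threshold
#'
#' The cutoff is chosen by exhaustive scan over the ensemble's scores at
#' the calibration points (presences and pseudo-absences); cells with
#' `di >= threshold` become presence.
#'
#' @param fit an [EnsembleFit-class].
#' @return list with `binary` (a logical-valued [GridLayer-class]) and
#'   `map` (the [SuitabilityMap-class] with the chosen threshold stored,
#'   for provenance).
#' @export
binarize <- function(fit) {
  pres <- fit@calibY
  # ensemble score at calibration points = weighted learner predictions
  w <- fit@map@weights
  sc <- rep(0, nrow(fit@calibX))
  for (nm in names(w)) {
    i <- which(vapply(fit@learners, `[[`, character(1), "id") == nm)
    sc <- sc + w[[nm]] *
      fit@learners[[i]]$predict(fit@models[[i]], fit@calibX)
  }
  th <- tssThreshold(sc, pres)
  di <- fit@map@di@values
  bin <- !is.na(di) & di >= th$threshold
  bin[is.na(di)] <- NA
  map <- fit@map
  map@threshold <- th$threshold
  list(binary = new("GridLayer", values = bin + 0, grid = fit@map@di@grid,
                    name = paste0(fit@map@speciesId, "_binary")),
       map = map, tss = th$tss)
}

#' Stack binary species maps into a richness raster
#'
#' Per-cell count of species whose binary suitability map is positive.
#'
#' @param binaryMaps list of [GridLayer-class] binary (0/1) rasters on a
#'   shared grid.
#' @return a [RichnessMap-class].
#' @export
stackRichness <- function(binaryMaps) {
  if (!length(binaryMaps)) stop("no maps to stack")
  g <- binaryMaps[[1]]@grid
  for (m in binaryMaps)
    if (!gridsIdentical(m@grid, g)) stop("all maps must share one grid")
  counts <- Reduce(`+`, lapply(binaryMaps, function(m) {
    v <- m@values; v[is.na(v)] <- 0; v
  }))
  new("RichnessMap", values = counts, grid = g, name = "richness",
      nSpecies = length(binaryMaps))
}

#' Permutation importance of each predictor
#'
#' The mean drop in calibration AUC of the ensemble score when a
#' predictor's column is randomly permuted, averaged over `repeats`
#' shuffles; larger drops mean larger contributions. Seeded and
#' reproducible.
#'
#' @param fit an [EnsembleFit-class].
#' @param repeats shuffles per variable (default 5).
#' @param seed integer seed.
#' @return data.frame with `variable`, `importance` (AUC drop) and `rank`,
#'   sorted by rank.
#' @export
rankVariableImportance <- function(fit, repeats = 5, seed) {
  ids <- vapply(fit@learners, `[[`, character(1), "id")
  w <- fit@map@weights
  score <- function(X) {
    sc <- rep(0, nrow(X))
    for (nm in names(w)) {
      i <- which(ids == nm)
      sc <- sc + w[[nm]] * fit@learners[[i]]$predict(fit@models[[i]], X)
    }
    sc
  }
  base <- computeAUC(score(fit@calibX), fit@calibY)
  vars <- colnames(fit@calibX)
  withSeed(seed, {
    imp <- vapply(vars, function(v) {
      drops <- vapply(seq_len(repeats), function(r) {
        Xp <- fit@calibX
        Xp[, v] <- sample(Xp[, v])
        base - computeAUC(score(Xp), fit@calibY)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    out <- data.frame(variable = vars, importance = imp)
    out <- out[order(-out$importance), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  })
}
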