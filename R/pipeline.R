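#' Assemble and validate a pipeline configuration
#'
#' Defaults mirror the analysis constants: density floor 10 vessel-hours,
#' AUC cutoff 0.9, collinearity cutoff 0.7, hotspot percentiles
#' 90/95/99/99.5, 5-fold cross-validation repeated 10 times. The default
#' run is fully synthetic: a seeded world supplies traffic, predictors,
#' occurrences and sites.
#'
#' @param seed master seed for the run.
#' @param outdir output directory (created if needed).
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` of the synthetic
#'   region.
#' @param resFine,resCoarse grid resolutions in degrees; `resFine` must be
#'   strictly finer.
#' @param nSpecies number of synthetic species.
#' @param nOccurrences presence records sampled per species.
#' @param nVars synthetic predictors (incl. distance from shore).
#' @param nLanes synthetic shipping corridors.
#' @param sites counts `c(points, smallPolys, largePolys)`.
#' @param floorHours density-index floor.
#' @param rCutoff collinearity screen cutoff.
#' @param aucCutoff ensemble admission AUC.
#' @param k,repeats cross-validation layout.
#' @param percentiles hotspot percentiles, each in (0, 100).
#' @param hotspotPercentile the percentile used for the overlap map.
#' @return validated config (list with class `shipstrikeConfig`).
#' @export
runConfig <- function(seed = 1, outdir = tempfile("shipstrike_run_"),
                      extent = c(-20, 20, -20, 20),
                      resFine = 0.1, resCoarse = 0.25,
                      nSpecies = 3, nOccurrences = 2000, nVars = 10,
                      nLanes = 3, sites = c(30, 10, 10),
                      floorHours = 10, rCutoff = 0.7, aucCutoff = 0.9,
                      k = 5, repeats = 10,
                      percentiles = c(90, 95, 99, 99.5),
                      hotspotPercentile = 99) {
  if (resFine <= 0 || resCoarse <= 0) stop("resolutions must be positive")
  if (resFine >= resCoarse)
    stop("fine resolution must be strictly finer than the coarse one")
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie strictly between 0 and 100")
  if (!hotspotPercentile %in% percentiles)
    stop("hotspotPercentile must be one of the configured percentiles")
  structure(list(seed = as.integer(seed), outdir = outdir,
                 extent = extent, resFine = resFine, resCoarse = resCoarse,
                 nSpecies = nSpecies, nOccurrences = nOccurrences,
                 nVars = nVars, nLanes = nLanes, sites = sites,
                 floorHours = floorHours, rCutoff = rCutoff,
                 aucCutoff = aucCutoff, k = k, repeats = repeats,
                 percentiles = sort(percentiles),
                 hotspotPercentile = hotspotPercentile),
            class = "shipstrikeConfig")
}

# Niche templates for the synthetic species: sharp logistic responses
# whose core habitat covers a modest fraction of the sea, the kind of
# strongly structured distribution the ensemble is meant to model.
# Recycled when more species are requested.
speciesCoefTemplates <- function(vars) {
  tpl <- function(ic, ...) {
    v <- c(...)
    list(coef = v[names(v) %in% vars], intercept = ic)
  }
  list(
    tpl(-10, SST = 8, DS = -4),
    tpl(-8, SST = -7, Chl = 4, DS = -3),
    tpl(-9, Bat = 6, SST = 4, Chl = -3),
    tpl(-7, DS = -6, MLD = 4),
    tpl(-9, SST = 5, MLD = -5, Bat = -3))
}

#' Run the full synthetic collision-risk pipeline
#'
#' Generates a seeded world, then runs every stage in order: traffic
#' gridding and intensity/density indices, site pressure assignment with
#' jurisdiction classification and summaries, per-species ensemble habitat
#' suitability, binary stacking into richness, collision risk, percentile
#' hotspots and multi-species overlap. All outputs land in
#' `config$outdir` and are listed, with MD5 checksums, in the returned
#' manifest (also written as `manifest.json`). Reruns with the same config
#' produce bit-identical outputs.
#'
#' @param config a config from [runConfig()].
#' @param quiet suppress stage messages.
#' @return the manifest, invisibly (list).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "shipstrikeConfig"))
  t0 <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  ex <- config$extent
  log <- list()

  say("[synth] building world (seed %d)", config$seed)
  world <- syntheticWorld(config$seed, ex[1], ex[2], ex[3], ex[4],
                          config$resFine, config$resCoarse)
  env <- makeEnvStack(world, nVars = config$nVars)
  traffic <- makeTraffic(world, nLanes = config$nLanes)
  sites <- makeSites(world, config$sites[1], config$sites[2],
                     config$sites[3])

  say("[pressure] intensity levels and density index")
  intensity <- classifyIntensity(traffic)
  vi <- computeDensityIndex(traffic, floorHours = config$floorHours)
  writeAsciiGrid(traffic, file.path(config$outdir, "traffic_hours.asc"))
  writeAsciiGrid(intensity, file.path(config$outdir, "intensity_level.asc"))
  writeAsciiGrid(vi, file.path(config$outdir, "density_vi.asc"))

  say("[zonation] site pressure and jurisdiction")
  sites <- assignSitePressure(sites, traffic)
  sites <- classifyJurisdiction(sites, world@highSeas)
  pressSummary <- summarizePressure(sites)
  log$sitesExcluded <- sites@table[sites@table$excluded,
                                   c("site_id", "exclude_reason")]
  writeSitesGeoJSON(sites, file.path(config$outdir, "sites.geojson"))
  jsonlite::write_json(pressSummary,
                       file.path(config$outdir, "site_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  say("[sdm] collinearity screen")
  sel <- selectVariables(env, cutoff = config$rCutoff)
  log$droppedVariables <- sel$dropped
  envSel <- sel$env

  coefs <- speciesCoefTemplates(names(env@layers))
  aligned <- NULL
  binaries <- list(); masks <- list(); evalRows <- list()
  for (s in seq_len(config$nSpecies)) {
    spId <- sprintf("species_%02d", s)
    say("[sdm] %s: occurrences, ensemble, risk", spId)
    tpl <- coefs[[((s - 1) %% length(coefs)) + 1]]
    truth <- makeTrueSuitability(env, tpl$coef, intercept = tpl$intercept,
                                 speciesId = spId)
    occ <- sampleOccurrences(truth, config$nOccurrences,
                             seed = childSeed(config$seed,
                                              paste0("occ", s)))
    writeOccurrences(occ, file.path(config$outdir,
                                    paste0("occurrences_", spId, ".csv")))
    occ <- thinOccurrences(occ)
    fit <- fitSuitability(occ, envSel, k = config$k,
                          repeats = config$repeats,
                          aucCutoff = config$aucCutoff,
                          seed = childSeed(config$seed, paste0("fit", s)))
    for (ev in fit@evals)
      evalRows[[length(evalRows) + 1]] <-
        data.frame(species = spId, learner = ev@learnerId,
                   auc = ev@auc, tss = ev@tss)
    bin <- binarize(fit)
    binaries[[spId]] <- bin$binary
    writeAsciiGrid(bin$map@di, file.path(config$outdir,
                                         paste0("di_", spId, ".asc")))
    if (is.null(aligned)) aligned <- alignGrids(vi, bin$map)$vi
    risk <- computeRisk(aligned, bin$map)
    writeAsciiGrid(risk, file.path(config$outdir,
                                   paste0("risk_", spId, ".asc")))
    masks[[spId]] <- hotspotMask(risk,
                                 percentile = config$hotspotPercentile)
  }
  evalTab <- do.call(rbind, evalRows)
  utils::write.csv(evalTab, file.path(config$outdir, "evaluation.csv"),
                   row.names = FALSE)

  say("[stack] richness and hotspot overlap")
  richness <- stackRichness(binaries)
  writeAsciiGrid(richness, file.path(config$outdir, "richness.asc"))
  overlap <- overlapHotspots(masks)
  writeAsciiGrid(overlap, file.path(config$outdir, "hotspot_overlap.asc"))
  ovSummary <- overlapSummary(overlap)
  utils::write.csv(ovSummary$exact,
                   file.path(config$outdir, "overlap_summary.csv"),
                   row.names = FALSE)

  files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
  manifest <- list(
    package = "shipstrike",
    version = as.character(utils::packageVersion("shipstrike")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    exclusions = list(
      sites = if (nrow(log$sitesExcluded)) log$sitesExcluded else list(),
      droppedVariables = log$droppedVariables),
    evaluation = evalTab,
    outputs = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(config$outdir, files)))))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  say("[done] %d outputs in %s", length(files) + 1, config$outdir)
  invisible(manifest)
}
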