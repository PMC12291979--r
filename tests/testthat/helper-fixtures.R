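# Shared fixtures, built in code at test time.

# a tiny all-sea world for fast geometry/statistics tests
tinyWorld <- function(seed = 1, size = 10) {
  syntheticWorld(seed, xmin = 0, xmax = size, ymin = 0, ymax = size,
                 resFine = size / 100, resCoarse = size / 40)
}

# a GridLayer from a bare matrix on a unit-cell grid anchored at (0, 0)
layerFromMatrix <- function(m, res = 1) {
  g <- gridSpec4326(0, ncol(m) * res, 0, nrow(m) * res, res)
  new("GridLayer", values = m, grid = g, name = "test")
}

trafficFromMatrix <- function(m, res = 1) {
  l <- layerFromMatrix(m, res)
  trafficGrid(l@values, l@grid)
}

# independent point-in-polygon oracle (interior points; mgcv semantics
# are undefined exactly on the boundary, so oracle comparisons jitter
# points off edges)
oraclePointInPolygon <- function(lon, lat, poly) {
  as.logical(mgcv::in.out(rbind(poly, poly[1, ]), cbind(lon, lat)))
}

# exhaustive pairwise AUC oracle: mean over all presence-absence pairs
oracleAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  sp <- scores[labels]; sn <- scores[!labels]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# brute-force TSS-maximizing threshold scan
oracleTssThreshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  tss <- sapply(cand, function(t) computeTSS(scores >= t, labels))
  cand[which.max(tss)]
}

# risk map wrapper around a bare matrix
riskFromMatrix <- function(m, res = 1) {
  l <- layerFromMatrix(m, res)
  new("RiskMap", values = l@values, grid = l@grid, name = "risk",
      speciesId = "sp", provenance = c(vi = "v", di = "d"))
}

suitabilityFromMatrix <- function(m, grid, speciesId = "sp") {
  new("SuitabilityMap", speciesId = speciesId,
      di = new("GridLayer", values = m, grid = grid, name = "di"),
      weights = c(one = 1), threshold = NA_real_)
}
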