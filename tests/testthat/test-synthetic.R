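test_that("identical seeds give bit-identical worlds and inputs", {
  w1 <- tinyWorld(3); w2 <- tinyWorld(3)
  expect_identical(w1@landFine, w2@landFine)
  expect_identical(makeEnvStack(w1)@layers, makeEnvStack(w2)@layers)
  t1 <- makeTraffic(w1); t2 <- makeTraffic(w2)
  expect_identical(gridValues(t1), gridValues(t2))
  s1 <- makeSites(w1, 5, 3, 2); s2 <- makeSites(w2, 5, 3, 2)
  expect_identical(s1@geometry, s2@geometry)
  truth <- makeTrueSuitability(makeEnvStack(w1), c(SST = 8, DS = -4),
                               intercept = -10)
  o1 <- sampleOccurrences(truth, 50, seed = 9)
  o2 <- sampleOccurrences(truth, 50, seed = 9)
  expect_identical(o1@records, o2@records)
})

test_that("environmental stack carries its designed structure", {
  w <- syntheticWorld(1)
  env <- makeEnvStack(w, nVars = 9)
  expect_length(env@layers, 9)
  expect_true("DS" %in% names(env@layers))
  # the designated collinear pair
  r <- cor(as.vector(env@layers$SST), as.vector(env@layers$Sal),
           use = "complete.obs")
  expect_gt(abs(r), 0.7)
  # distance from shore: positive on sea, NA on land
  expect_true(all(is.na(env@layers$DS[w@landCoarse])))
  expect_true(all(env@layers$DS[!w@landCoarse] > 0))
  expect_error(makeEnvStack(w, nVars = 1), "at least 2")
  expect_error(
    makeEnvStack(syntheticWorld(1, xmin = 0, xmax = 0.2, ymin = 0,
                                ymax = 0.2, resFine = 0.1,
                                resCoarse = 0.2)),
    "degenerate")
})

test_that("an all-sea mask yields the sentinel maximum distance", {
  g <- gridSpec4326(0, 5, 0, 5, 1)
  d <- distanceFromShore(matrix(FALSE, 5, 5), g)
  expect_true(all(d == d[1, 1]))
  expect_equal(d[1, 1], sqrt((5 * 111.32)^2 + (5 * 110.57)^2))
})

test_that("true suitability is the inverse-logit of the standardized blend", {
  w <- tinyWorld(5)
  env <- makeEnvStack(w, nVars = 4)
  # zero coefficients: constant 0.5 everywhere at sea
  t0 <- makeTrueSuitability(env, c(SST = 0))
  expect_true(all(abs(gridValues(t0)[!w@landCoarse] - 0.5) < 1e-12))
  # saturating coefficient approximates the predictor-sign indicator
  tBig <- makeTrueSuitability(env, c(SST = 1e4))
  z <- scale(as.vector(env@layers$SST))[, 1]
  surf <- as.vector(gridValues(tBig))
  sea <- !is.na(surf) & abs(z) > 1e-3
  expect_true(all(surf[sea][z[sea] > 0] > 0.999))
  expect_true(all(surf[sea][z[sea] < 0] < 0.001))
  expect_error(makeTrueSuitability(env, c(NotAVar = 1)), "unknown")

  # spot-check five cells against a hand recomputation
  cf <- c(SST = 1.3, Chl = -0.7)
  tt <- makeTrueSuitability(env, cf, intercept = 0.2)
  zS <- scale(as.vector(env@layers$SST))[, 1]
  zC <- scale(as.vector(env@layers$Chl))[, 1]
  expectSurf <- 1 / (1 + exp(-(0.2 + 1.3 * zS - 0.7 * zC)))
  got <- as.vector(gridValues(tt))
  cells <- which(!is.na(got))[c(1, 7, 23, 101, 399)]
  expect_equal(got[cells], expectSurf[cells])
})

test_that("occurrence sampling follows the suitability surface", {
  w <- tinyWorld(11)
  env <- makeEnvStack(w, nVars = 3)
  truth <- makeTrueSuitability(env, c(SST = 2))
  expect_error(sampleOccurrences(truth, 0, seed = 1), "at least 1")
  o1 <- sampleOccurrences(truth, 1, seed = 4)
  expect_equal(nrow(o1@records), 1L)
  idx <- cellIndexOf(truth@surface@grid, o1@records$lon, o1@records$lat)
  expect_false(is.na(gridValues(truth)[idx$row, idx$col]))

  # degenerate surface: all mass in one cell
  surf <- gridValues(truth) * 0
  surf[13, 17] <- 1
  deg <- truth; deg@surface@values <- surf
  od <- sampleOccurrences(deg, 25, seed = 5)
  idx <- cellIndexOf(truth@surface@grid, od@records$lon, od@records$lat)
  expect_true(all(idx$row == 13 & idx$col == 17))

  # empirical cell frequency tracks the truth surface
  o <- sampleOccurrences(truth, 2000, seed = 7)
  idx <- cellIndexOf(truth@surface@grid, o@records$lon, o@records$lat)
  cell <- (idx$col - 1) * nRows(truth@surface@grid) + idx$row
  freq <- tabulate(cell, nbins = length(gridValues(truth)))
  p <- as.vector(gridValues(truth))
  sea <- !is.na(p)
  expect_gt(cor(freq[sea], p[sea], method = "spearman"), 0.5)
})

test_that("per-cell sampling frequencies match the truth (chi-square)", {
  w <- tinyWorld(13)
  env <- makeEnvStack(w, nVars = 3)
  truth <- makeTrueSuitability(env, c(SST = 1.5))
  p <- as.vector(gridValues(truth))
  sea <- which(!is.na(p))
  o <- sampleOccurrences(truth, 50000, seed = 21)
  idx <- cellIndexOf(truth@surface@grid, o@records$lon, o@records$lat)
  cell <- (idx$col - 1) * nRows(truth@surface@grid) + idx$row
  counts <- tabulate(cell, nbins = length(p))
  pick <- sea[seq(1, length(sea), length.out = 10)]
  probs <- p[pick] / sum(p[sea])
  obs <- c(counts[pick], 50000 - sum(counts[pick]))
  gof <- suppressWarnings(
    chisq.test(obs, p = c(probs, 1 - sum(probs))))
  expect_gt(gof$p.value, 0.01)
})

test_that("synthetic traffic honors its construction contracts", {
  w <- syntheticWorld(1)
  tr <- makeTraffic(w)
  h <- gridValues(tr)
  expect_true(all(h[w@landFine] == 0))
  sea <- h[!w@landFine]
  expect_gte(max(sea) / min(sea[sea > 0]), 1e4)
  lev <- gridValues(classifyIntensity(tr))[!w@landFine]
  expect_true(all(1:7 %in% lev))  # every nonzero level populated

  tr0 <- makeTraffic(w, nLanes = 0)
  expect_equal(sum(tr0@laneMask), 0L)
  sea0 <- gridValues(tr0)[!w@landFine]
  expect_gte(max(sea0) / min(sea0[sea0 > 0]), 1e2)
  expect_error(makeTraffic(w, nLanes = -1), "nonnegative")
})

test_that("synthetic sites meet their constructive guarantees", {
  w <- syntheticWorld(2)
  s <- makeSites(w, nPoints = 4, nSmallPolys = 3, nLargePolys = 2)
  expect_equal(nrow(s@table), 9L)
  small <- which(startsWith(s@table$site_id, "SP"))
  for (i in small) {
    span <- apply(s@geometry[[i]], 2, function(v) diff(range(v)))
    expect_true(all(span < 0.1))
  }
  # the forced straddler really is transboundary, and is never an MPA
  s <- classifyJurisdiction(s, w@highSeas)
  last <- which(s@table$site_id == "LP002")
  expect_equal(s@table$jurisdiction[last], "transboundary")
  expect_true(s@table$category[last] %in% c("EBSA", "IMMA"))

  empty <- makeSites(w, 0, 0, 0)
  expect_equal(nrow(empty@table), 0L)
  expect_true(validObject(empty))
})
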