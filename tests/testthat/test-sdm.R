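mkOcc <- function(lon, lat, date, grid, sp = "sp") {
  new("OccurrenceSet", speciesId = sp,
      records = data.frame(lon = lon, lat = lat, date = as.Date(date)),
      grid = grid, thinned = FALSE)
}

test_that("spatial thinning keeps one earliest record per cell", {
  g <- gridSpec4326(0, 10, 0, 10, 1)
  occ <- mkOcc(c(1.1, 1.5, 1.9, 5.5),
               c(1.1, 1.5, 1.9, 5.5),
               c("2010-05-01", "2001-01-01", "2015-12-31", "2012-06-15"), g)
  th <- thinOccurrences(occ)
  expect_equal(nrow(th@records), 2L)
  # earliest date won in the triple cell
  expect_true(as.Date("2001-01-01") %in% th@records$date)
  # idempotence
  expect_identical(thinOccurrences(th)@records, th@records)

  # 500 uniform records against a brute-force group-by oracle
  set.seed(8)
  n <- 500
  occ2 <- mkOcc(runif(n, 0, 10), runif(n, 0, 10),
                as.Date("2000-01-01") + sample(3650, n, TRUE), g)
  th2 <- thinOccurrences(occ2)
  idx <- cellIndexOf(g, occ2@records$lon, occ2@records$lat)
  cell <- paste(idx$row, idx$col)
  oracle <- do.call(rbind, lapply(split(occ2@records, cell), function(d)
    d[order(d$date)[1], ]))
  expect_equal(nrow(th2@records), length(unique(cell)))
  expect_setequal(paste(th2@records$lon, th2@records$date),
                  paste(oracle$lon, oracle$date))
})

test_that("range filtering equals point-in-polygon brute force", {
  g <- gridSpec4326(0, 10, 0, 10, 1)
  sq <- rbind(c(2, 2), c(8, 2), c(8, 8), c(2, 8))
  inside <- mkOcc(c(3, 5), c(3, 5), c("2010-01-01", "2011-01-01"), g)
  expect_equal(nrow(filterByRange(inside, list(sq))@records), 2L)
  outside <- mkOcc(c(1, 9), c(1, 9), c("2010-01-01", "2011-01-01"), g)
  expect_warning(out <- filterByRange(outside, list(sq)), "outside")
  expect_equal(nrow(out@records), 0L)
  expect_error(filterByRange(inside, list()), "empty")

  set.seed(4)
  mixed <- mkOcc(runif(200, 0, 10), runif(200, 0, 10),
                 rep("2010-01-01", 200), g)
  got <- filterByRange(mixed, list(sq))@records
  keep <- oraclePointInPolygon(mixed@records$lon, mixed@records$lat, sq)
  expect_equal(nrow(got), sum(keep))
  expect_setequal(got$lon, mixed@records$lon[keep])
})

test_that("collinearity screen removes exactly the violating structure", {
  w <- tinyWorld(2)
  env <- makeEnvStack(w, nVars = 6)
  # duplicate layer: exactly one of the pair survives
  env2 <- new("EnvStack",
              layers = c(env@layers["Chl"], list(Chl2 = env@layers$Chl)),
              grid = env@grid)
  sel2 <- selectVariables(env2)
  expect_length(sel2$dropped, 1)
  expect_length(sel2$env@layers, 1)
  # nothing dropped when all pairs are below the cutoff
  indep <- new("EnvStack", layers = env@layers[c("Chl", "MLD", "SIT")],
               grid = env@grid)
  expect_length(selectVariables(indep)$dropped, 0)
  # after screening, no remaining pair violates the cutoff
  sel <- selectVariables(env, cutoff = 0.7)
  X <- sapply(sel$env@layers, as.vector)
  r <- abs(cor(X, use = "pairwise.complete.obs"))
  diag(r) <- 0
  expect_true(all(r <= 0.7))
  expect_error(selectVariables(env, cutoff = 1.3), "cutoff")
})

test_that("pseudo-absences avoid presences and respect the seed", {
  w <- tinyWorld(6)
  env <- makeEnvStack(w, nVars = 3)
  truth <- makeTrueSuitability(env, c(SST = 2))
  occ <- thinOccurrences(sampleOccurrences(truth, 300, seed = 2))
  pa <- generatePseudoAbsences(occ, env, seed = 5)
  expect_equal(nrow(pa), nrow(occ@records))  # balanced by default
  expect_identical(pa, generatePseudoAbsences(occ, env, seed = 5))
  # no sampled background cell holds a presence
  g <- env@grid
  pc <- with(cellIndexOf(g, occ@records$lon, occ@records$lat),
             paste(row, col))
  ac <- with(cellIndexOf(g, pa$lon, pa$lat), paste(row, col))
  expect_length(intersect(pc, ac), 0)
  expect_error(generatePseudoAbsences(occ, env, nPA = 1e6, seed = 1),
               "candidate cells")
})

test_that("AUC matches the exhaustive pairwise oracle", {
  expect_equal(computeAUC(c(1, 2, 3, 10, 11, 12),
                          c(F, F, F, T, T, T)), 1)
  expect_equal(computeAUC(rep(0.3, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  expect_error(computeAUC(1:4, rep(TRUE, 4)), "both classes")
  set.seed(12)
  for (i in 1:50) {
    sc <- sample(round(runif(12), 2))  # rounded to force some ties
    lab <- rep(c(TRUE, FALSE), each = 6)
    expect_equal(computeAUC(sc, lab), oracleAUC(sc, lab))
  }
  # independent library cross-check on a larger tied sample
  set.seed(13)
  sc <- round(runif(300), 1)
  lab <- rbinom(300, 1, plogis(3 * sc - 1.5))
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(lab, sc, direction = "<", quiet = TRUE))))
  expect_equal(computeAUC(sc, lab), ref)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  sc <- rnorm(40)
  lab <- rep(c(TRUE, FALSE), 20)
  a <- computeAUC(sc, lab)
  expect_equal(computeAUC(exp(sc), lab), a)
  expect_equal(computeAUC(rank(sc), lab), a)
})

test_that("TSS is sensitivity plus specificity minus one", {
  y <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(computeTSS(y, y), 1)
  # sensitivity 0.9, specificity 0.8
  pred <- y; pred[1] <- FALSE; pred[11:12] <- TRUE
  expect_equal(computeTSS(pred, y), 0.9 + 0.8 - 1)
  expect_equal(computeTSS(!pred, y), -computeTSS(pred, y))
  expect_error(computeTSS(pred, rep(TRUE, 20)), "both classes")
})

test_that("TSS-maximizing threshold matches the exhaustive scan", {
  set.seed(15)
  for (i in 1:20) {
    sc <- round(runif(20), 2)
    lab <- c(rep(TRUE, 10), rep(FALSE, 10))
    got <- tssThreshold(sc, lab)
    expect_equal(got$threshold, oracleTssThreshold(sc, lab))
  }
  expect_error(tssThreshold(rep(0.4, 10), rep(c(T, F), 5)), "degenerate")
})

test_that("cross-validation separates oracle from random learners", {
  w <- tinyWorld(3)
  env <- makeEnvStack(w, nVars = 4)
  truth <- makeTrueSuitability(env, c(SST = 8, Chl = -4), intercept = -6)
  occ <- thinOccurrences(sampleOccurrences(truth, 400, seed = 1))
  pa <- generatePseudoAbsences(occ, env, seed = 2)
  X <- rbind(envValuesAt(env, occ@records$lon, occ@records$lat),
             envValuesAt(env, pa$lon, pa$lat))
  y <- rep(c(TRUE, FALSE), c(nrow(occ@records), nrow(pa)))
  ok <- complete.cases(X); X <- X[ok, ]; y <- y[ok]

  ev <- crossValidate(makeLogisticLearner(), X, y, k = 5, repeats = 10,
                      seed = 3)
  expect_gt(ev@auc, 0.9)
  expect_equal(nrow(attr(ev, "foldValues")), 50L)  # k x repeats folds

  randomLearner <- list(id = "random",
                        fit = function(X, y) NULL,
                        predict = function(m, X) runif(nrow(X)))
  i200 <- c(which(y)[1:100], which(!y)[1:100])
  evR <- crossValidate(randomLearner, X[i200, ], y[i200], k = 5,
                       repeats = 10, seed = 4)
  expect_lt(abs(evR@auc - 0.5), 0.1)
  expect_error(crossValidate(makeLogisticLearner(), X[1:6, ], y[1:6],
                             k = 5, repeats = 1, seed = 1), "at least")
})

test_that("ensemble weighting admits only high-AUC learners", {
  g <- gridSpec4326(0, 2, 0, 2, 1)
  p <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  q <- matrix(c(0.5, 0.6, 0.7, 0.8), 2, 2)
  r <- matrix(0.9, 2, 2)
  ev <- function(id, auc) new("EvaluationRecord", learnerId = id,
                              auc = auc, tss = 0.5, folds = 5L,
                              repeats = 10L)
  # a single passing learner is returned verbatim with weight 1
  m1 <- buildEnsemble(list(a = p), list(ev("a", 0.95)), g)
  expect_equal(gridValues(m1), p)
  expect_equal(unname(m1@weights), 1)
  # equal AUCs average the projections
  m2 <- buildEnsemble(list(a = p, b = q),
                      list(ev("a", 0.93), ev("b", 0.93)), g)
  expect_equal(gridValues(m2), (p + q) / 2)
  # AUC {0.95, 0.92, 0.80}: third excluded, weights auc-proportional
  m3 <- buildEnsemble(list(a = p, b = q, c = r),
                      list(ev("a", 0.95), ev("b", 0.92), ev("c", 0.80)),
                      g)
  expect_equal(unname(m3@weights), c(0.95, 0.92) / 1.87)
  expect_false("c" %in% names(m3@weights))
  expect_equal(gridValues(m3),
               (0.95 * p + 0.92 * q) / 1.87)
  expect_error(buildEnsemble(list(a = p), list(ev("a", 0.85)), g),
               "relaxing aucCutoff")
})

test_that("binarization stores the scan threshold and matches truth when separable", {
  w <- tinyWorld(4)
  env <- makeEnvStack(w, nVars = 4)
  truth <- makeTrueSuitability(env, c(SST = 8, DS = -4), intercept = -8)
  occ <- thinOccurrences(sampleOccurrences(truth, 400, seed = 6))
  fit <- fitSuitability(occ, env, repeats = 2, seed = 7)
  bin <- binarize(fit)
  expect_false(is.na(bin$map@threshold))
  # the stored threshold is the exhaustive-scan optimum on the
  # calibration scores
  ids <- sapply(fit@learners, `[[`, "id")
  sc <- rep(0, nrow(fit@calibX))
  for (nm in names(fit@map@weights)) {
    i <- which(ids == nm)
    sc <- sc + fit@map@weights[[nm]] *
      fit@learners[[i]]$predict(fit@models[[i]], fit@calibX)
  }
  expect_equal(bin$map@threshold, oracleTssThreshold(sc, fit@calibY))
  v <- gridValues(bin$binary)
  expect_true(all(v[!is.na(v)] %in% c(0, 1)))
})

test_that("richness stacking counts species per cell", {
  g <- gridSpec4326(0, 3, 0, 3, 1)
  ones <- lapply(1:9, function(i)
    new("GridLayer", values = matrix(1, 3, 3), grid = g, name = "b"))
  expect_true(all(gridValues(stackRichness(ones)) == 9))
  disjoint <- lapply(1:3, function(i) {
    m <- matrix(0, 3, 3); m[i, i] <- 1
    new("GridLayer", values = m, grid = g, name = "b")
  })
  expect_equal(max(gridValues(stackRichness(disjoint))), 1)
  # random maps: vectorized stack equals an explicit cell loop
  set.seed(2)
  rnd <- lapply(1:5, function(i)
    new("GridLayer", values = matrix(rbinom(9, 1, 0.5), 3, 3), grid = g,
        name = "b"))
  got <- gridValues(stackRichness(rnd))
  oracle <- matrix(0, 3, 3)
  for (r in 1:3) for (cl in 1:3)
    for (m in rnd) oracle[r, cl] <- oracle[r, cl] + m@values[r, cl]
  expect_equal(got, oracle)
  g2 <- gridSpec4326(0, 6, 0, 6, 2)
  bad <- new("GridLayer", values = matrix(1, 3, 3), grid = g2, name = "b")
  expect_error(stackRichness(c(ones, list(bad))), "share one grid")
})

test_that("permutation importance recovers the synthetic drivers", {
  w <- tinyWorld(8)
  env <- makeEnvStack(w, nVars = 6)
  # Chl drives the species; MLD and SIT are noise
  truth <- makeTrueSuitability(env, c(Chl = 8, MLD = 0), intercept = -6)
  occ <- thinOccurrences(sampleOccurrences(truth, 500, seed = 3))
  envUse <- new("EnvStack", layers = env@layers[c("Chl", "MLD", "SIT")],
                grid = env@grid)
  fit <- fitSuitability(occ, envUse,
                        learners = list(makeLogisticLearner()),
                        repeats = 2, seed = 4)
  imp <- rankVariableImportance(fit, repeats = 5, seed = 5)
  expect_equal(imp$variable[imp$rank == 1], "Chl")
  expect_lt(abs(imp$importance[imp$variable == "MLD"]), 0.05)
  expect_identical(imp, rankVariableImportance(fit, repeats = 5, seed = 5))
})
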