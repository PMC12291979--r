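test_that("point pressure is the Moore-neighborhood maximum", {
  h <- matrix(0, 5, 5)
  h[2:4, 2:4] <- matrix(c(1, 2, 3, 4, 99, 5, 6, 7, 8), 3, 3)
  tr <- trafficFromMatrix(h)
  # center cell (3,3) holds 99 but is excluded; max of the ring is 8
  expect_equal(assignPointPressure(2.5, 2.5, tr), 8)
  expect_equal(assignPointPressure(2.5, 2.5, tr, includeCenter = TRUE), 99)
  # grid corner: only the 3 existing neighbors count
  h2 <- matrix(seq_len(25), 5, 5)
  tr2 <- trafficFromMatrix(h2)
  expect_equal(assignPointPressure(0.5, 0.5, tr2),
               max(h2[cbind(c(2, 1, 2), c(1, 2, 2))]))
  # exclusion contracts
  out <- assignPointPressure(99, 99, tr)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "outside_extent")
  trNA <- trafficFromMatrix(matrix(NA_real_, 5, 5))
  out2 <- assignPointPressure(2.5, 2.5, trNA)
  expect_equal(attr(out2, "reason"), "no_traffic_coverage")
})

test_that("polygon pressure averages covered cell centers", {
  h <- matrix(c(10, 20, 30, 40), 2, 2)
  tr <- trafficFromMatrix(h)
  rect <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(assignPolygonPressure(rect, tr), 25)
  # a sub-cell polygon delegates to the point rule at its centroid
  w <- tinyWorld(1)
  trW <- makeTraffic(w)
  tiny <- rbind(c(5.01, 5.01), c(5.06, 5.01), c(5.06, 5.06), c(5.01, 5.06))
  expect_equal(assignPolygonPressure(tiny, trW),
               assignPointPressure(5.035, 5.035, trW))
  expect_error(assignPolygonPressure(rbind(c(0, 0), c(1, 1)), tr),
               "invalid polygon")
})

test_that("L-shaped polygon mean equals the point-in-polygon oracle", {
  set.seed(3)
  h <- matrix(runif(25, 0, 100), 5, 5)
  tr <- trafficFromMatrix(h)
  L <- rbind(c(0.2, 0.2), c(4.8, 0.2), c(4.8, 1.8), c(1.8, 1.8),
             c(1.8, 4.8), c(0.2, 4.8))
  got <- assignPolygonPressure(L, tr)
  cc <- cellCenters(tr@grid)
  grid <- expand.grid(row = 1:5, col = 1:5)
  inside <- oraclePointInPolygon(cc$lon[grid$col], cc$lat[grid$row], L)
  expect_equal(got, mean(h[cbind(grid$row, grid$col)][inside]))
})

test_that("jurisdiction classification uses boundary intersection", {
  hs <- list(rbind(c(5, 0), c(10, 0), c(10, 10), c(5, 10)))
  mk <- function(geom, cat, gtype) {
    new("SiteSet",
        table = data.frame(site_id = "s1", category = cat,
                           geom_type = gtype, stringsAsFactors = FALSE),
        geometry = list(geom))
  }
  inside <- rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2))
  straddle <- rbind(c(4, 4), c(6, 4), c(6, 6), c(4, 6))
  expect_equal(classifyJurisdiction(mk(inside, "EBSA", "polygon"),
                                    hs)@table$jurisdiction, "national")
  expect_equal(classifyJurisdiction(mk(straddle, "EBSA", "polygon"),
                                    hs)@table$jurisdiction, "transboundary")
  # a point exactly on the boundary line intersects it
  expect_equal(classifyJurisdiction(mk(c(5, 3), "IMMA", "point"),
                                    hs)@table$jurisdiction, "transboundary")
  # MPAs are assumed absent from the high seas
  expect_equal(classifyJurisdiction(mk(straddle, "MPA", "polygon"),
                                    hs)@table$jurisdiction, "national")
})

test_that("pressure summaries reproduce printed count tables", {
  # reported per-level EBSA counts and shares
  tab <- data.frame(category = "EBSA",
                    level = rep(1:6, c(2, 61, 109, 96, 46, 5)))
  s <- summarizePressure(tab)
  expect_equal(s$byLevel$n, c(2, 61, 109, 96, 46, 5))
  expect_equal(s$byLevel$pct, c(0.63, 19.12, 34.17, 30.09, 14.42, 1.57))
  # low-to-moderate (levels up to 4) aggregate is 84%
  lowMod <- sum(s$byLevel$pct[s$byLevel$level <= 4])
  expect_equal(round(lowMod), 84)
  # a single site carries 100% of its level
  one <- summarizePressure(data.frame(category = "IMMA", level = 5))
  expect_equal(one$byLevel$pct, 100)
  # transboundary share: 11 of 268 sites
  jt <- data.frame(category = "IMMA",
                   jurisdiction = rep(c("transboundary", "national"),
                                      c(11, 257)))
  expect_equal(jurisdictionShare(jt), 4.10)
})

test_that("count shares sum to 100 and area shares ignore ordering", {
  set.seed(11)
  tab <- data.frame(category = sample(c("MPA", "EBSA"), 200, TRUE),
                    level = sample(0:7, 200, TRUE),
                    area_km2 = runif(200, 1, 1e4))
  tab$stress <- stressClass(tab$level)
  s <- summarizePressure(tab)
  for (cat in unique(tab$category)) {
    expect_lt(abs(sum(s$byLevel$pct[s$byLevel$category == cat]) - 100),
              0.05)
    expect_lt(abs(sum(s$byStress$pct[s$byStress$category == cat]) - 100),
              0.05)
  }
  s2 <- summarizePressure(tab[sample(nrow(tab)), ])
  expect_equal(s$byStress$pctArea, s2$byStress$pctArea)
  # empty input is an empty summary, not an error
  expect_equal(summarizePressure(tab[0, ])$nExcluded, 0L)
})

test_that("raising every cell's hours never lowers a site's level", {
  w <- tinyWorld(5)
  tr <- makeTraffic(w, nLanes = 2)
  sites <- makeSites(w, 10, 5, 5)
  a <- assignSitePressure(sites, tr)@table
  trUp <- trafficGrid(gridValues(tr) * 3 + 1, tr@grid)
  b <- assignSitePressure(sites, trUp)@table
  ok <- !a$excluded & !b$excluded
  expect_true(all(b$level[ok] >= a$level[ok]))
})

test_that("excluded sites are reported, never silently dropped", {
  h <- matrix(NA_real_, 5, 5); h[1, 1] <- 50
  tr <- trafficFromMatrix(h)
  sites <- new("SiteSet",
               table = data.frame(site_id = c("a", "b"),
                                  category = c("MPA", "EBSA"),
                                  geom_type = c("point", "point"),
                                  stringsAsFactors = FALSE),
               geometry = list(c(3.5, 3.5), c(1.5, 0.5)))
  out <- assignSitePressure(sites, tr)
  expect_true(out@table$excluded[1])     # all-NA neighborhood
  expect_false(out@table$excluded[2])    # sees the (1,1) cell
  s <- summarizePressure(out)
  expect_equal(s$nExcluded, 1L)
})
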