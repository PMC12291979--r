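# Synthetic study region and inputs. Everything here is seeded and
# deterministic: one SyntheticWorld seed fixes the coastline, predictors,
# occurrences, traffic and sites drawn from it.

canonicalEnvNames <- c("SST", "Sal", "Chl", "MLD", "SIT", "SSH", "SIC",
                       "Bat", "TS", "TA")

#' Build a synthetic study region
#'
#' Creates a square region with a fine grid for vessel traffic, a coarse
#' grid for environmental predictors, a procedurally drawn single-landmass
#' coastline along the western edge (so "distance from shore" and coastal
#' shipping lanes are meaningful), and a high-seas boundary: waters east of
#' a fixed fraction of the extent stand in for areas beyond national
#' jurisdiction.
#'
#' @param seed integer; fully determines the world and (by default) all
#'   draws derived from it.
#' @param xmin,xmax,ymin,ymax extent in degrees (default a 40 x 40 degree
#'   region, 400 x 400 fine cells and 160 x 160 coarse cells).
#' @param resFine,resCoarse cell sizes of the traffic and predictor grids.
#' @param highSeasFraction fraction of the zonal extent, measured from the
#'   west, at which the high-seas boundary runs.
#' @return a [SyntheticWorld-class].
#' @examples
#' w <- syntheticWorld(seed = 1)
#' w
#' @export
syntheticWorld <- function(seed, xmin = -20, xmax = 20, ymin = -20,
                           ymax = 20, resFine = 0.1, resCoarse = 0.25,
                           highSeasFraction = 0.7) {
  gf <- gridSpec4326(xmin, xmax, ymin, ymax, resFine)
  gc <- gridSpec4326(xmin, xmax, ymin, ymax, resCoarse)
  if (nRows(gf) < 2 || nCols(gf) < 2)
    stop("degenerate extent: the grid must have more than one cell per axis")
  width <- xmax - xmin
  coast <- withSeed(childSeed(seed, "coast"), {
    # smooth wavy coastline around 22% of the width from the west edge
    amp <- stats::runif(4, 0.01, 0.035) * width
    phase <- stats::runif(4, 0, 2 * pi)
    freq <- 1:4
    function(lat) {
      t <- (lat - ymin) / (ymax - ymin)
      x <- xmin + 0.22 * width
      for (i in 1:4) x <- x + amp[i] * sin(2 * pi * freq[i] * t + phase[i])
      pmin(pmax(x, xmin + 0.08 * width), xmin + 0.38 * width)
    }
  })
  landOn <- function(g) {
    cc <- cellCenters(g)
    outer(coast(cc$lat), cc$lon, function(cl, lon) lon < cl)
  }
  landFine <- landOn(gf)
  xb <- xmin + highSeasFraction * width
  highSeas <- list(rbind(c(xb, ymin), c(xmax, ymin),
                         c(xmax, ymax), c(xb, ymax)))
  new("SyntheticWorld", gridFine = gf, gridCoarse = gc,
      landFine = landFine, landCoarse = landOn(gc),
      highSeas = highSeas, seed = as.integer(seed))
}

#' Distance from shore
#'
#' For every sea cell, the distance (km, equirectangular approximation on
#' cell centers) to the nearest coastline cell, where the coastline is the
#' set of land cells with at least one sea cell in their 4-neighborhood.
#' Land cells are `NA`. With no land at all, every cell carries the
#' sentinel maximum: the diagonal of the grid extent.
#'
#' @param land logical land mask matrix (TRUE = land).
#' @param grid the matching [GridSpec-class].
#' @return numeric matrix of distances in km.
#' @export
distanceFromShore <- function(land, grid) {
  cc <- cellCenters(grid)
  ny <- nRows(grid); nx <- nCols(grid)
  out <- matrix(NA_real_, ny, nx)
  sea <- !land
  diagKm <- sqrt(((grid@xmax - grid@xmin) * 111.32)^2 +
                 ((grid@ymax - grid@ymin) * 110.57)^2)
  if (!any(land)) { out[] <- diagKm; return(out) }
  if (!any(sea)) return(out)
  # coastline = land cells adjacent to sea
  pad <- function(m, fill) {
    r <- matrix(fill, nrow(m) + 2, ncol(m) + 2)
    r[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    r
  }
  p <- pad(sea, FALSE)
  seaAdj <- p[1:ny, 2:(nx + 1)] | p[3:(ny + 2), 2:(nx + 1)] |
    p[2:(ny + 1), 1:nx] | p[2:(ny + 1), 3:(nx + 2)]
  coastCells <- which(land & seaAdj, arr.ind = TRUE)
  if (nrow(coastCells) == 0) { out[sea] <- diagKm; return(out) }
  seaCells <- which(sea, arr.ind = TRUE)
  kmLat <- 110.57
  kmLon <- 111.32 * cos(pi * (cc$lat[seaCells[, 1]] +
                              cc$lat[coastCells[1, 1]]) / 360)
  bx <- cc$lon[coastCells[, 2]]; by <- cc$lat[coastCells[, 1]]
  sx <- cc$lon[seaCells[, 2]];  sy <- cc$lat[seaCells[, 1]]
  best <- rep(Inf, nrow(seaCells))
  chunk <- 256L
  for (s in seq(1L, nrow(coastCells), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(coastCells))
    dx <- outer(sx, bx[s:e], "-") * kmLon
    dy <- outer(sy, by[s:e], "-") * kmLat
    best <- pmin(best, sqrt(dx * dx + dy * dy)[cbind(
      seq_len(nrow(seaCells)),
      max.col(-(dx * dx + dy * dy), ties.method = "first"))])
  }
  out[sea] <- best
  out
}

#' Generate a stack of synthetic environmental predictors
#'
#' Spatially autocorrelated fields (Gaussian-smoothed white noise, kernel
#' sd `sigma` coarse cells) on the world's coarse grid, named after the
#' standard predictor set (SST, Sal, Chl, MLD, SIT, SSH, SIC, Bat, TS, TA)
#' with distance from shore (DS) always included as the final layer,
#' derived from the land mask. SST additionally carries a meridional
#' (latitude) gradient, and Sal is constructed from SST so the pair is
#' strongly collinear (|r| > 0.7), giving the collinearity screen
#' something to remove. All layers are `NA` on land.
#'
#' @param world a [SyntheticWorld-class].
#' @param nVars total number of predictors including DS (>= 2).
#' @param sigma smoothing kernel sd in coarse cells.
#' @param seed integer; defaults to a child of the world seed.
#' @return an [EnvStack-class].
#' @export
makeEnvStack <- function(world, nVars = 10, sigma = 5,
                         seed = childSeed(world@seed, "env")) {
  if (nVars < 2) stop("nVars must be at least 2")
  g <- world@gridCoarse
  if (nRows(g) < 2 || nCols(g) < 2)
    stop("degenerate extent: the grid must have more than one cell per axis")
  if (nVars - 1 > length(canonicalEnvNames))
    stop(sprintf("at most %d predictors supported",
                 length(canonicalEnvNames) + 1))
  nms <- c(canonicalEnvNames[seq_len(nVars - 1)], "DS")
  ny <- nRows(g); nx <- nCols(g)
  land <- world@landCoarse
  cc <- cellCenters(g)
  layers <- withSeed(seed, {
    smooth <- function() {
      m <- gaussSmooth(matrix(stats::rnorm(ny * nx), ny, nx), sigma)
      matrix(zscore(as.vector(m)), ny, nx)
    }
    out <- list()
    for (nm in nms) {
      if (nm == "DS") {
        out[[nm]] <- distanceFromShore(land, g)
      } else if (nm == "SST") {
        lat <- matrix(cc$lat, ny, nx)
        out[[nm]] <- 25 - 0.45 * abs(lat - (g@ymin + g@ymax) / 2) +
          3 * smooth()
      } else if (nm == "Sal" && "SST" %in% nms) {
        out[[nm]] <- 34 + 0.9 * zscore(as.vector(out[["SST"]])) +
          0.3 * smooth()
      } else {
        out[[nm]] <- smooth()
      }
    }
    if (!all(c("SST", "Sal") %in% nms)) {
      # two-variable stack: tie the first predictor to DS instead
      ds <- out[["DS"]]
      z <- matrix(zscore(as.vector(ds)), ny, nx)
      z[is.na(z)] <- 0
      out[[nms[1]]] <- 0.9 * z + 0.3 * smooth()
    }
    out
  })
  layers <- lapply(layers, function(m) { m[land] <- NA_real_; m })
  new("EnvStack", layers = layers, grid = g)
}

#' Define a ground-truth suitability surface
#'
#' The inverse-logit of a linear combination of z-scored predictors:
#' `logit(p) = intercept + sum(coef_v * z(env_v))`. This is the surface
#' occurrences are sampled from and the reference that ensemble recovery is
#' judged against.
#'
#' @param env an [EnvStack-class].
#' @param coefficients named numeric vector; names must be a subset of the
#'   stack's layer names.
#' @param intercept scalar offset on the logit scale.
#' @param speciesId label for the synthetic species.
#' @return a [TrueSuitability-class].
#' @export
makeTrueSuitability <- function(env, coefficients, intercept = 0,
                                speciesId = "synthetic_whale") {
  unknown <- setdiff(names(coefficients), names(env@layers))
  if (length(unknown))
    stop("unknown predictor name(s): ", paste(unknown, collapse = ", "))
  ny <- nRows(env@grid); nx <- nCols(env@grid)
  eta <- matrix(intercept, ny, nx)
  for (nm in names(coefficients)) {
    z <- matrix(zscore(as.vector(env@layers[[nm]])), ny, nx)
    eta <- eta + coefficients[[nm]] * z
  }
  surf <- invLogit(eta)
  new("TrueSuitability", speciesId = speciesId,
      coefficients = coefficients,
      surface = new("GridLayer", values = surf, grid = env@grid,
                    name = "true_suitability"))
}

#' Sample presence records from a known suitability surface
#'
#' Draws `n` presence records from sea cells with probability proportional
#' to the suitability value, with replacement (real sighting records
#' repeat within cells, so spatial thinning has work to do), and places
#' each record uniformly within its cell with a random date in 1994-2024.
#'
#' @param truth a [TrueSuitability-class].
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @return an [OccurrenceSet-class] (unthinned).
#' @export
sampleOccurrences <- function(truth, n, seed) {
  if (n < 1) stop("n must be at least 1")
  g <- truth@surface@grid
  w <- as.vector(truth@surface@values)
  ok <- which(!is.na(w) & w > 0)
  if (!length(ok))
    stop("no sea cells with positive suitability to sample from")
  ny <- nRows(g)
  withSeed(seed, {
    cells <- ok[sample.int(length(ok), n, replace = TRUE, prob = w[ok])]
    row <- ((cells - 1L) %% ny) + 1L
    col <- ((cells - 1L) %/% ny) + 1L
    lon <- g@xmin + (col - 1L + stats::runif(n)) * g@res
    lat <- g@ymin + (row - 1L + stats::runif(n)) * g@res
    date <- as.Date("1994-01-01") +
      sample.int(as.integer(as.Date("2024-12-31") - as.Date("1994-01-01")),
                 n, replace = TRUE)
    new("OccurrenceSet", speciesId = truth@speciesId,
        records = data.frame(lon = lon, lat = lat, date = date),
        grid = g, thinned = FALSE)
  })
}

#' Generate synthetic vessel-activity hours
#'
#' A heavy-tailed, coastally concentrated traffic field on the world's fine
#' grid: a log-normal background (smoothed log-hours noise spanning several
#' orders of magnitude) overlaid with `nLanes` high-intensity corridors
#' running parallel to the coast at increasing offsets. Land cells carry
#' exactly 0 hours. Under the defaults the field spans more than four
#' orders of magnitude so every intensity level 1-7 is populated.
#'
#' @param world a [SyntheticWorld-class].
#' @param nLanes number of coastal corridors (>= 0).
#' @param seed integer seed.
#' @return a [TrafficGrid-class]; its `laneMask` slot records the corridor
#'   cells for recovery experiments.
#' @export
makeTraffic <- function(world, nLanes = 3,
                        seed = childSeed(world@seed, "traffic")) {
  if (nLanes < 0) stop("nLanes must be nonnegative")
  g <- world@gridFine
  ny <- nRows(g); nx <- nCols(g)
  land <- world@landFine
  cc <- cellCenters(g)
  withSeed(seed, {
    noise <- gaussSmooth(matrix(stats::rnorm(ny * nx), ny, nx), 8)
    z <- matrix(zscore(as.vector(noise)), ny, nx)
    loghours <- 1.5 + 1.3 * z
    # horizontal offshore offset (degrees) of each sea cell from the
    # easternmost land cell in its latitude band
    coastLon <- apply(land, 1, function(r)
      if (any(r)) cc$lon[max(which(r))] else g@xmin - g@res)
    offshore <- sweep(matrix(cc$lon, ny, nx, byrow = TRUE), 1, coastLon)
    laneMask <- matrix(FALSE, ny, nx)
    if (nLanes > 0) {
      wiggle <- gaussSmooth1d(stats::rnorm(ny), 20)
      wiggle <- 0.4 * (wiggle - mean(wiggle)) / max(stats::sd(wiggle), 1e-9)
      for (k in seq_len(nLanes)) {
        center <- 1.5 + 2.5 * (k - 1)
        inLane <- abs(sweep(offshore, 1, wiggle) - center) < 0.3
        laneMask <- laneMask | (inLane & !land)
      }
      laneInt <- 5.6 + 0.9 * matrix(zscore(as.vector(
        gaussSmooth(matrix(stats::rnorm(ny * nx), ny, nx), 12))), ny, nx)
      loghours[laneMask] <- pmax(loghours[laneMask], laneInt[laneMask])
    }
    hours <- 10^loghours
    hours[land] <- 0
    new("TrafficGrid", values = hours, grid = g, name = "vessel_hours",
        laneMask = laneMask)
  })
}

#' Generate synthetic protected sites
#'
#' Point sites, sub-cell polygons (bounding box under 0.1 degree in both
#' axes, so pressure assignment simplifies them to points) and large
#' polygons, with categories drawn from MPA / EBSA / IMMA. When at least
#' one large polygon is requested, the last one is forced to straddle the
#' high-seas boundary (and is never an MPA, which are assumed absent from
#' the high seas), so jurisdiction classification has a guaranteed
#' transboundary case.
#'
#' @param world a [SyntheticWorld-class].
#' @param nPoints,nSmallPolys,nLargePolys site counts (>= 0 each).
#' @param seed integer seed.
#' @return a [SiteSet-class]; all-zero counts give a valid empty set.
#' @export
makeSites <- function(world, nPoints = 30, nSmallPolys = 10,
                      nLargePolys = 10,
                      seed = childSeed(world@seed, "sites")) {
  stopifnot(nPoints >= 0, nSmallPolys >= 0, nLargePolys >= 0)
  g <- world@gridFine
  sea <- which(!world@landFine, arr.ind = TRUE)
  cc <- cellCenters(g)
  xb <- world@highSeas[[1]][1, 1]
  withSeed(seed, {
    geoms <- list(); ids <- character(); cats <- character()
    gty <- character()
    rcat <- function(n, pool = c("MPA", "EBSA", "IMMA"))
      sample(pool, n, replace = TRUE)
    seaSpot <- function() {
      i <- sample.int(nrow(sea), 1)
      c(cc$lon[sea[i, 2]], cc$lat[sea[i, 1]])
    }
    rect <- function(center, w, h) {
      rbind(c(center[1] - w / 2, center[2] - h / 2),
            c(center[1] + w / 2, center[2] - h / 2),
            c(center[1] + w / 2, center[2] + h / 2),
            c(center[1] - w / 2, center[2] + h / 2))
    }
    clampRect <- function(r) {
      r[, 1] <- pmin(pmax(r[, 1], g@xmin), g@xmax - 1e-9)
      r[, 2] <- pmin(pmax(r[, 2], g@ymin), g@ymax - 1e-9)
      r
    }
    k <- 0L
    for (i in seq_len(nPoints)) {
      k <- k + 1L
      geoms[[k]] <- seaSpot()
      ids <- c(ids, sprintf("PT%03d", i)); gty <- c(gty, "point")
    }
    cats <- c(cats, rcat(nPoints))
    for (i in seq_len(nSmallPolys)) {
      k <- k + 1L
      geoms[[k]] <- clampRect(rect(seaSpot(), stats::runif(1, 0.02, 0.09),
                                   stats::runif(1, 0.02, 0.09)))
      ids <- c(ids, sprintf("SP%03d", i)); gty <- c(gty, "polygon")
    }
    cats <- c(cats, rcat(nSmallPolys))
    for (i in seq_len(nLargePolys)) {
      k <- k + 1L
      if (i == nLargePolys) {
        # force a transboundary polygon across the high-seas line
        ctr <- c(xb, stats::runif(1, g@ymin + 3, g@ymax - 3))
        geoms[[k]] <- clampRect(rect(ctr, stats::runif(1, 2, 5),
                                     stats::runif(1, 2, 5)))
        cats <- c(cats, rcat(1, c("EBSA", "IMMA")))
      } else {
        geoms[[k]] <- clampRect(rect(seaSpot(), stats::runif(1, 1, 6),
                                     stats::runif(1, 1, 6)))
        cats <- c(cats, rcat(1))
      }
      ids <- c(ids, sprintf("LP%03d", i)); gty <- c(gty, "polygon")
    }
    tab <- data.frame(site_id = ids, category = cats, geom_type = gty,
                      stringsAsFactors = FALSE)
    new("SiteSet", table = tab, geometry = geoms)
  })
}
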