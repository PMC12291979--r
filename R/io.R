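# Standard-format I/O. Rasters travel as ESRI ASCII grid (.asc): a plain
# text header (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value)
# followed by rows north to south. Values are written with 17 significant
# digits so a write/read round trip is bit-identical for doubles.

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param layer a [GridLayer-class] (or subclass).
#' @param path output file path.
#' @param nodata value standing for missing cells (default -9999).
#' @export
writeAsciiGrid <- function(layer, path, nodata = -9999) {
  g <- layer@grid
  v <- layer@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nCols(g)),
    sprintf("nrows %d", nRows(g)),
    sprintf("xllcorner %.10f", g@xmin),
    sprintf("yllcorner %.10f", g@ymin),
    sprintf("cellsize %.10f", g@res),
    sprintf("NODATA_value %s", formatC(nodata, format = "g"))), con)
  for (r in rev(seq_len(nrow(v)))) {  # north first
    row <- v[r, ]
    row[is.na(row)] <- nodata
    writeLines(paste(formatC(row, format = "g", digits = 17),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a [GridLayer-class]; cells equal to the file's NODATA value
#'   come back as `NA`, never as zero.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  ny <- hdr$nrows; nx <- hdr$ncols
  if (length(vals) != ny * nx) stop("cell count does not match header")
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
  m <- m[rev(seq_len(ny)), , drop = FALSE]  # back to south-first rows
  m[m == nodata] <- NA_real_
  g <- gridSpec4326(hdr$xllcorner, hdr$xllcorner + nx * hdr$cellsize,
                    hdr$yllcorner, hdr$yllcorner + ny * hdr$cellsize,
                    hdr$cellsize)
  new("GridLayer", values = m, grid = g,
      name = sub("\\.asc$", "", basename(path)))
}

#' Read occurrence records from CSV
#'
#' Expects columns `species`, `lon`, `lat`, `date`. Rows with unparseable
#' coordinates or dates, coordinates outside valid ranges, or dates before
#' `minDate` are dropped, with per-reason counts reported via `message()`.
#'
#' @param path CSV file path.
#' @param grid the analysis [GridSpec-class] the records are referenced
#'   to.
#' @param minDate earliest admissible date (default "1993-01-01",
#'   matching the temporal coverage of the environmental predictors);
#'   `NULL` disables the filter.
#' @return an [OccurrenceSet-class] (single species per file).
#' @export
readOccurrences <- function(path, grid, minDate = as.Date("1993-01-01")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "date")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  n0 <- nrow(df)
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  date <- suppressWarnings(as.Date(df$date))
  badCoord <- is.na(lon) | is.na(lat) | lon < -180 | lon >= 180 |
    lat < -90 | lat > 90
  badDate <- is.na(date)
  early <- if (is.null(minDate)) rep(FALSE, n0) else
    (!badDate & date < as.Date(minDate))
  drop <- badCoord | badDate | early
  if (any(drop))
    message(sprintf(
      "readOccurrences: dropped %d of %d rows (%d bad coordinates, %d bad dates, %d before %s)",
      sum(drop), n0, sum(badCoord), sum(badDate & !badCoord),
      sum(early & !badCoord), as.character(minDate)))
  keep <- which(!drop)
  new("OccurrenceSet",
      speciesId = if (length(keep)) df$species[keep[1]] else "unknown",
      records = data.frame(lon = lon[keep], lat = lat[keep],
                           date = date[keep]),
      grid = grid, thinned = FALSE)
}

#' Write occurrence records to CSV
#' @param occ an [OccurrenceSet-class].
#' @param path output path.
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(
    data.frame(species = occ@speciesId, lon = occ@records$lon,
               lat = occ@records$lat, date = as.character(occ@records$date)),
    path, row.names = FALSE)
  invisible(path)
}

#' Write protected sites as a GeoJSON FeatureCollection
#'
#' Point sites become Point features, polygon sites Polygon features
#' (ring closed on write); `site_id`, `category` and any assigned
#' pressure columns travel as feature properties.
#'
#' @param sites a [SiteSet-class].
#' @param path output path.
#' @export
writeSitesGeoJSON <- function(sites, path) {
  tab <- sites@table
  features <- lapply(seq_len(nrow(tab)), function(i) {
    geom <- sites@geometry[[i]]
    gj <- if (is.matrix(geom)) {
      ring <- rbind(geom, geom[1, , drop = FALSE])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(j) ring[j, ])))
    } else {
      list(type = "Point", coordinates = geom)
    }
    props <- as.list(tab[i, setdiff(names(tab), "geom_type"),
                         drop = FALSE])
    list(type = "Feature", properties = props, geometry = gj)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read protected sites from GeoJSON
#'
#' @param path a FeatureCollection of Point and Polygon features with
#'   `site_id` and `category` properties.
#' @return a [SiteSet-class].
#' @export
readSitesGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection")
  geoms <- list(); rows <- list()
  for (i in seq_along(fc$features)) {
    ft <- fc$features[[i]]
    g <- ft$geometry
    if (identical(g$type, "Point")) {
      geoms[[i]] <- as.numeric(unlist(g$coordinates))
      gtype <- "point"
    } else if (identical(g$type, "Polygon")) {
      ring <- do.call(rbind, lapply(g$coordinates[[1]], as.numeric))
      if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
        ring <- ring[-nrow(ring), , drop = FALSE]
      geoms[[i]] <- ring
      gtype <- "polygon"
    } else stop("unsupported geometry type: ", g$type)
    p <- ft$properties
    rows[[i]] <- data.frame(
      site_id = as.character(p$site_id),
      category = as.character(p$category),
      geom_type = gtype, stringsAsFactors = FALSE)
  }
  new("SiteSet", table = do.call(rbind, rows), geometry = geoms)
}
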