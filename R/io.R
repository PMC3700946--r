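# Readers, writers and run configuration. One CSV dialect throughout: comma
# separated, UTF-8, ISO-8601 UTC timestamps. No raw Argos data were deposited
# with the study this pipeline reproduces, so this dialect is the package's
# input contract.

LC_LEVELS <- c("3", "2", "1", "0", "A", "B", "Z")

#' Assemble an Argos track table
#'
#' @param turtle_id character vector of animal ids.
#' @param timestamp POSIXct (UTC) fix times.
#' @param lc Argos location class, one of 3, 2, 1, 0, A, B, Z.
#' @param lat,lon fix coordinates, decimal degrees WGS84.
#' @return a data.frame of class `argostrack`, sorted by (turtle_id, timestamp),
#'   exact duplicate rows removed.
#' @export
argosTrack <- function(turtle_id, timestamp, lc, lat, lon) {
  lc <- as.character(lc)
  bad <- !lc %in% LC_LEVELS
  if (any(bad)) stop("unknown location class: ", paste(unique(lc[bad]), collapse = ", "))
  checkLatLon(lat, lon)
  if (!inherits(timestamp, "POSIXct")) stop("timestamp must be POSIXct (UTC)")
  attr(timestamp, "tzone") <- "UTC"
  df <- data.frame(
    turtle_id = as.character(turtle_id), timestamp = timestamp,
    lc = lc, lat = lat, lon = lon, stringsAsFactors = FALSE
  )
  df <- unique(df)
  df <- df[order(df$turtle_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("argostrack", "data.frame")
  df
}

#' Read an Argos track CSV
#'
#' Columns `turtle_id, timestamp, lc, lat, lon`; timestamps ISO-8601 UTC.
#' Rows with unparseable coordinates or timestamps are rejected with a logged
#' count; exact duplicates are dropped; output is stably sorted by
#' (turtle_id, timestamp).
#'
#' @param path CSV file path.
#' @param quiet suppress the log message about dropped rows.
#' @return an `argostrack` data.frame.
#' @export
readTrackCsv <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) stop("empty track file: ", path)
  need <- c("turtle_id", "timestamp", "lc", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("track CSV missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  ok <- !is.na(ts) & is.finite(lat) & is.finite(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180 & df$lc %in% LC_LEVELS
  if (any(!ok) && !quiet) {
    message(sum(!ok), " unparseable row(s) rejected from ", basename(path))
  }
  if (!any(ok)) stop("no parseable rows in ", path)
  argosTrack(df$turtle_id[ok], ts[ok], df$lc[ok], lat[ok], lon[ok])
}

#' Write an Argos track CSV
#' @param track an `argostrack` data.frame.
#' @param path output path.
#' @return invisibly `path`.
#' @export
writeTrackCsv <- function(track, path) {
  out <- data.frame(
    turtle_id = track$turtle_id,
    timestamp = format(track$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lc = track$lc,
    lat = sprintf("%.6f", track$lat),
    lon = sprintf("%.6f", track$lon)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read beach emergence events
#'
#' Columns `turtle_id, date, site_label, lat, lon, kind` with kind in
#' \{nest, false_crawl\}.
#' @param path CSV file path.
#' @return data.frame with `date` as Date, sorted by (turtle_id, date).
#' @export
readEmergenceCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("turtle_id", "date", "site_label", "lat", "lon", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("emergence CSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- !df$kind %in% c("nest", "false_crawl")
  if (any(bad)) stop("unknown emergence kind: ", paste(unique(df$kind[bad]), collapse = ", "))
  df$date <- as.Date(df$date)
  checkLatLon(df$lat, df$lon)
  df <- df[order(df$turtle_id, df$date), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read an oil/gas platform table
#'
#' Columns `platform_id, lat, lon` and optional `removal_date` (empty = still
#' active).
#' @param path CSV file path.
#' @return data.frame with logical column `active`.
#' @export
readPlatformCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("platform_id", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("platform CSV missing column(s): ", paste(miss, collapse = ", "))
  checkLatLon(df$lat, df$lon)
  if (!"removal_date" %in% names(df)) df$removal_date <- NA_character_
  df$active <- is.na(df$removal_date) | df$removal_date == ""
  df
}

# ---- configuration ----------------------------------------------------------

#' Pipeline run configuration
#'
#' All tunables of the analysis with their defaults: 5 km/h swim-speed limit,
#' -200 m neritic cutoff, 8-h state-space interval, MCMC settings (2 chains,
#' 10000 iterations, 7000 burn-in, thin 5), KDE probability levels 0.50/0.95,
#' KDE eligibility of >= 20 mean daily locations, 100 site-fidelity
#' replicates, 5-km nest-fidelity radius, 10-km occupancy grid cells, 10-km
#' platform buffer, behavioural-mode cutoffs 1.25/1.75, the two-chain mixing
#' threshold 1.1, and the per-location-class t-error constants (degrees of
#' freedom and scale in km) shared by the simulator and the state-space model.
#'
#' @param ... named overrides of any default.
#' @return a validated list of class `runconfig`.
#' @export
runConfig <- function(...) {
  cfg <- list(
    speedLimitKmh = 5,
    neriticCutoffM = -200,
    ssmIntervalHours = 8,
    mcmcChains = 2,
    mcmcIterations = 10000,
    mcmcBurnin = 7000,
    mcmcThin = 5,
    kdeLevels = c(0.50, 0.95),
    minMeanDailyLocations = 20,
    fidelityReplicates = 100,
    nestFidelityRadiusKm = 5,
    gridCellKm = 10,
    platformBufferKm = 10,
    modeCutoffLow = 1.25,
    modeCutoffHigh = 1.75,
    rhatThreshold = 1.1,
    lcErrorDf = c("3" = 10, "2" = 8, "1" = 6, "0" = 4, "A" = 4, "B" = 3),
    lcErrorScaleKm = c(
      "3" = 0.25, "2" = 0.4, "1" = 0.8, "0" = 1.7,
      "A" = 1.0, "B" = 1.9
    ),
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validateConfig(cfg)
  class(cfg) <- "runconfig"
  cfg
}

validateConfig <- function(cfg) {
  pos <- c(
    "speedLimitKmh", "ssmIntervalHours", "mcmcChains", "mcmcIterations",
    "mcmcThin", "fidelityReplicates", "nestFidelityRadiusKm",
    "gridCellKm", "platformBufferKm", "rhatThreshold"
  )
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0)) stop(f, " must be positive")
  }
  if (cfg$neriticCutoffM >= 0) stop("neriticCutoffM must be negative")
  if (cfg$mcmcBurnin < 0 || cfg$mcmcBurnin >= cfg$mcmcIterations + cfg$mcmcBurnin + 1) {
    stop("mcmcBurnin must be non-negative")
  }
  if (any(cfg$kdeLevels <= 0 | cfg$kdeLevels >= 1)) stop("kdeLevels must lie in (0, 1)")
  if (!(cfg$modeCutoffLow > 1 && cfg$modeCutoffHigh < 2 &&
    cfg$modeCutoffLow < cfg$modeCutoffHigh)) {
    stop("mode cutoffs must satisfy 1 < low < high < 2")
  }
  if (!identical(sort(names(cfg$lcErrorDf)), sort(setdiff(LC_LEVELS, "Z")))) {
    stop("lcErrorDf must name classes 3,2,1,0,A,B")
  }
  if (any(cfg$lcErrorDf <= 0) || any(cfg$lcErrorScaleKm <= 0)) {
    stop("LC error constants must be positive")
  }
  invisible(TRUE)
}

#' Write/read a run configuration (lossless JSON round trip)
#' @param cfg a `runconfig` list.
#' @param path file path.
#' @return `readRunConfig` returns a `runconfig`; `writeRunConfig` the path.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "runconfig"))
  out <- unclass(cfg)
  # keep location-class names through JSON (atomic-vector names drop otherwise)
  out$lcErrorDf <- as.list(out$lcErrorDf)
  out$lcErrorScaleKm <- as.list(out$lcErrorScaleKm)
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$kdeLevels <- as.numeric(raw$kdeLevels)
  raw$lcErrorDf <- unlist(raw$lcErrorDf)
  raw$lcErrorScaleKm <- unlist(raw$lcErrorScaleKm)
  do.call(runConfig, raw)
}

# ---- GeoJSON ----------------------------------------------------------------

ringSelfIntersects <- function(ring) {
  ring <- closeRing(as.matrix(ring))
  n <- nrow(ring) - 1L
  if (n < 3L) {
    return(TRUE)
  }
  seg <- function(i) list(p = ring[i, ], q = ring[i + 1L, ])
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next # adjacent via closure
      s1 <- seg(i)
      s2 <- seg(j)
      d1 <- orient(s1$p, s1$q, s2$p)
      d2 <- orient(s1$p, s1$q, s2$q)
      d3 <- orient(s2$p, s2$q, s1$p)
      d4 <- orient(s2$p, s2$q, s1$q)
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Build a GeoJSON feature
#'
#' @param geometry for `type = "Polygon"` a list of rings, each a 2-column
#'   (lon, lat) matrix; for `type = "Point"` a length-2 (lon, lat) vector.
#' @param properties named list of feature properties.
#' @param type geometry type.
#' @return a feature list suitable for [writeGeoJSON()].
#' @export
geojsonFeature <- function(geometry, properties = list(), type = c("Polygon", "Point")) {
  type <- match.arg(type)
  list(type = type, geometry = geometry, properties = properties)
}

#' Write features as RFC 7946 GeoJSON
#'
#' Coordinates are written in lon-lat order, WGS84. Polygon rings are closed
#' on output and validated (>= 4 closed vertices, no self-intersection) before
#' anything is written.
#'
#' @param features list of features from [geojsonFeature()]; may be empty.
#' @param path output path.
#' @return invisibly `path`.
#' @export
writeGeoJSON <- function(features, path) {
  out <- vector("list", length(features))
  for (i in seq_along(features)) {
    f <- features[[i]]
    if (f$type == "Polygon") {
      rings <- lapply(f$geometry, function(r) closeRing(as.matrix(r)))
      for (r in rings) {
        if (nrow(r) < 4) stop("polygon ring with fewer than 3 distinct vertices")
        if (ringSelfIntersects(r)) stop("self-intersecting polygon ring")
      }
      coords <- lapply(rings, function(r) {
        lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
      })
      geom <- list(type = "Polygon", coordinates = coords)
    } else {
      geom <- list(type = "Point", coordinates = c(f$geometry[1], f$geometry[2]))
    }
    props <- f$properties
    if (length(props) == 0) props <- stats::setNames(list(), character(0))
    out[[i]] <- list(type = "Feature", geometry = geom, properties = props)
  }
  fc <- list(type = "FeatureCollection", features = out)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8, null = "null")
  invisible(path)
}

#' Read a GeoJSON FeatureCollection written by [writeGeoJSON()]
#' @param path file path.
#' @return list of features in the [geojsonFeature()] layout.
#' @export
readGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(fc$features, function(f) {
    if (f$geometry$type == "Polygon") {
      rings <- lapply(f$geometry$coordinates, function(ring) {
        do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      })
      geojsonFeature(rings, f$properties, "Polygon")
    } else {
      geojsonFeature(
        c(f$geometry$coordinates[[1]], f$geometry$coordinates[[2]]),
        f$properties, "Point"
      )
    }
  })
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (2.5 -> 3), the convention used for
#' comparison against printed table values; base R's round() ties to even.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
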