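# Generative twin of the telemetry the pipeline analyses. No raw tracking
# data were deposited with the study this package re-implements, so
# validation runs on simulated tracks whose generative process is exactly the
# switching correlated random walk the state-space model assumes, observed at
# irregular Argos-like times through per-location-class Student-t errors, on
# a synthetic world with a straight meridional coastline and a linear shelf
# running from the beach to the -200 m isobath.

#' Simulation configuration
#'
#' Defaults follow the analysis conditions: 8-h process steps over 120 days;
#' movement persistence gamma = (0.8, 0.2), turn angles theta = (0, pi),
#' behavioural transition probabilities alpha = (0.95, 0.10) (state 1 =
#' migration); process noise 0.03 degrees per axis; Argos-like fix schedule of
#' 6 fixes/day with a location-class mixture weighted toward A and B;
#' re-nesting interval around 14 days; two beaches ~250 km apart for the
#' long-range nest-swap scenario; a shelf reaching -200 m 150 km offshore.
#'
#' @param ... named overrides.
#' @return list of class `simconfig`.
#' @export
simConfig <- function(...) {
  cfg <- list(
    gamma = c(0.8, 0.2),
    theta = c(0, pi),
    alpha = c(0.95, 0.10),
    sigma = c(0.03, 0.03), # process sd, degrees lon/lat
    psi = 1,
    durationDays = 120,
    intervalHours = 8,
    meanFixesPerDay = 6,
    lcProbs = c("3" = 0.05, "2" = 0.08, "1" = 0.12, "0" = 0.15, "A" = 0.25, "B" = 0.35),
    zFraction = 0.02, # junk LC Z fixes injected
    landOutlierFraction = 0.01, # fixes displaced onto land
    lcErrorDf = runConfig()$lcErrorDf,
    lcErrorScaleKm = runConfig()$lcErrorScaleKm,
    coastLon = 0, # land at lon >= coastLon
    shelfWidthKm = 150, # -200 m reached this far offshore
    beachLat = 29.0,
    beachSeparationKm = 250, # second beach along the coast
    startOffshoreKm = 20,
    startState = 2L, # tagged while nesting -> inter-nesting
    constrainToWater = TRUE, # FALSE = exact generative twin of the SSM process
    renestIntervalDays = 14,
    renestIntervalSd = 2,
    fidelityScenario = c("faithful"),
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown sim field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (abs(sum(cfg$lcProbs) - 1) > 1e-9) stop("lcProbs must sum to 1")
  stopifnot(
    cfg$durationDays > 0, cfg$meanFixesPerDay > 0, cfg$shelfWidthKm > 0,
    all(cfg$gamma >= 0 & cfg$gamma <= 1), all(cfg$alpha > 0 & cfg$alpha < 1),
    all(cfg$sigma >= 0), cfg$renestIntervalDays > 0
  )
  class(cfg) <- "simconfig"
  cfg
}

#' Analytic depth of the synthetic shelf
#'
#' Land (elevation +2 m) east of the coast meridian; westward the bottom
#' deepens linearly, crossing -200 m at `shelfWidthKm` offshore.
#' @param sim a `simConfig()`.
#' @param lat,lon query coordinates.
#' @return elevation in metres.
#' @export
shelfDepth <- function(sim, lat, lon) {
  kmPerDegLon <- (2 * pi * EARTH_RADIUS_KM / 360) * cos(sim$beachLat * pi / 180)
  offshoreKm <- (sim$coastLon - lon) * kmPerDegLon
  ifelse(offshoreKm <= 0, 2, -200 * offshoreKm / sim$shelfWidthKm)
}

#' Rasterise the synthetic shelf to a bathymetry grid
#'
#' @param sim a `simConfig()`.
#' @param lonRange,latRange grid extent in degrees.
#' @param cellsize cell edge in degrees (default 1 arc-minute, the native
#'   resolution of the global relief model the study used).
#' @return a `bathygrid`.
#' @export
simulateBathymetry <- function(sim, lonRange = c(-3.5, 0.5),
                               latRange = c(26.5, 31.5), cellsize = 1 / 60) {
  lon <- seq(lonRange[1] + cellsize / 2, lonRange[2] - cellsize / 2, by = cellsize)
  lat <- seq(latRange[1] + cellsize / 2, latRange[2] - cellsize / 2, by = cellsize)
  vals <- outer(lat, lon, function(la, lo) shelfDepth(sim, la, lo))
  bathymetryGrid(lonRange[1], latRange[1], cellsize, vals)
}

#' Simulate a switching-CRW track observed through Argos errors
#'
#' States follow the exact process the state-space model assumes; observations
#' are a known-position release fix at tagging time (LC 3; it also pins the
#' regularisation grid phase) followed by a Poisson-scheduled stream at
#' irregular times, linearly interpolated between bracketing states, with
#' per-class t noise. A configurable fraction of LC Z junk fixes and
#' land-side outliers is injected for filter testing. By default the latent
#' path is constrained to water by redrawing the process noise (up to 100
#' attempts, then reflecting the offending step off the coast); set
#' `constrainToWater = FALSE` for an exact generative twin of the fitted
#' model, e.g. in parameter-recovery studies (the coast boundary is outside
#' the model).
#'
#' @param sim a `simConfig()`.
#' @param startDate first state time (UTC).
#' @return list with `truth` (data.frame: time, lon, lat, state, mode per 8-h
#'   step) and `fixes` (an `argostrack`), plus the achieved parameters.
#' @export
simulateTrack <- function(sim = simConfig(), startDate = as.POSIXct("2012-06-01 00:00:00", tz = "UTC")) {
  set.seed(sim$seed)
  m <- as.integer(sim$durationDays * 24 / sim$intervalHours) + 1L
  if (sim$startOffshoreKm >= sim$shelfWidthKm) {
    stop("start position deeper than the shelf; shelf too narrow for the inter-nesting kernel")
  }
  kmPerDegLat <- 2 * pi * EARTH_RADIUS_KM / 360
  kmPerDegLon <- kmPerDegLat * cos(sim$beachLat * pi / 180)

  x <- matrix(NA_real_, m, 2) # lon, lat
  x[1, ] <- c(sim$coastLon - sim$startOffshoreKm / kmPerDegLon, sim$beachLat)
  b <- integer(m - 1) # 1 = migration, 2 = inter-nesting

  # behavioural chain
  b[1] <- sim$startState
  for (s in 2:(m - 1)) {
    pStay1 <- if (b[s - 1] == 1) sim$alpha[1] else sim$alpha[2]
    b[s] <- if (stats::runif(1) < pStay1) 1L else 2L
  }

  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  d <- c(0, 0)
  for (s in 1:(m - 1)) {
    k <- b[s]
    mu <- as.numeric(sim$gamma[k] * rot(sim$theta[k]) %*% d)
    if (sim$constrainToWater) {
      for (try in 1:100) {
        eta <- stats::rnorm(2, 0, sim$sigma)
        cand <- x[s, ] + mu + eta
        if (shelfDepth(sim, cand[2], cand[1]) < 0) break
        if (try == 100) {
          # reflect off the coast
          cand[1] <- 2 * sim$coastLon - cand[1] - 2 * (1 / kmPerDegLon)
        }
      }
    } else {
      cand <- x[s, ] + mu + stats::rnorm(2, 0, sim$sigma)
    }
    x[s + 1, ] <- cand
    d <- x[s + 1, ] - x[s, ]
  }
  times <- startDate + (seq_len(m) - 1L) * sim$intervalHours * 3600
  truth <- data.frame(
    time = times, lon = x[, 1], lat = x[, 2],
    state = c(NA_integer_, b),
    mode = c(NA, ifelse(b == 1, "migration", "internesting")),
    stringsAsFactors = FALSE
  )

  # observation schedule: a release fix at tagging (t = 0, good quality —
  # the release position is effectively known) then a Poisson-scheduled
  # stream at uniform times over the track span
  spanH <- (m - 1) * sim$intervalHours
  nObs <- max(2L, stats::rpois(1, sim$meanFixesPerDay * sim$durationDays))
  obsT <- c(0, sort(stats::runif(nObs - 1L, 0, spanH - 1e-6)))
  idx <- floor(obsT / sim$intervalHours) + 1L
  j <- obsT / sim$intervalHours - (idx - 1L)
  lc <- sample(names(sim$lcProbs), nObs, replace = TRUE, prob = sim$lcProbs)
  lc[1] <- "3"
  df <- unname(sim$lcErrorDf[lc])
  scKm <- unname(sim$lcErrorScaleKm[lc])
  lonObs <- (1 - j) * x[idx, 1] + j * x[idx + 1L, 1] +
    sim$psi * (scKm / kmPerDegLon) * stats::rt(nObs, df)
  latObs <- (1 - j) * x[idx, 2] + j * x[idx + 1L, 2] +
    sim$psi * (scKm / kmPerDegLat) * stats::rt(nObs, df)

  # junk and outlier injection
  # never corrupt the release fix: it anchors the regularisation grid
  nZ <- stats::rbinom(1, nObs - 1L, sim$zFraction)
  if (nZ > 0) {
    zi <- 1L + sample.int(nObs - 1L, nZ)
    lc[zi] <- "Z"
    lonObs[zi] <- lonObs[zi] + stats::rnorm(nZ, 0, 100 / kmPerDegLon)
    latObs[zi] <- latObs[zi] + stats::rnorm(nZ, 0, 100 / kmPerDegLat)
  }
  nL <- stats::rbinom(1, nObs - 1L, sim$landOutlierFraction)
  if (nL > 0) {
    li <- sample(setdiff(2:nObs, if (nZ > 0) zi else integer(0)),
      min(nL, nObs - 1L - nZ))
    lonObs[li] <- sim$coastLon + stats::runif(length(li), 0.05, 0.3)
  }
  latObs <- pmin(pmax(latObs, -89.9), 89.9)
  lonObs <- pmin(pmax(lonObs, -179.9), 179.9)

  fixes <- argosTrack(
    turtle_id = "sim01",
    timestamp = startDate + round(obsT * 3600),
    lc = lc, lat = latObs, lon = lonObs
  )
  list(truth = truth, fixes = fixes, sim = sim)
}

#' Simulate beach emergences from a simulated truth path
#'
#' Emergences are placed during inter-nesting phases at the configured
#' re-nesting interval. Under the `faithful` scenario successive events stay
#' within the 5-km nest-fidelity radius of the first beach; under `swap` they
#' alternate between two beaches separated by `beachSeparationKm`.
#'
#' @param sim a `simConfig()`.
#' @param truth the `truth` data.frame from [simulateTrack()].
#' @param scenario "faithful" or "swap".
#' @return emergence data.frame (turtle_id, date, site_label, lat, lon, kind).
#' @export
simulateEmergences <- function(sim, truth, scenario = c("faithful", "swap")) {
  scenario <- match.arg(scenario)
  set.seed(sim$seed + 1L)
  kmPerDegLat <- 2 * pi * EARTH_RADIUS_KM / 360
  beachA <- c(sim$beachLat, sim$coastLon)
  beachB <- c(sim$beachLat + sim$beachSeparationKm / kmPerDegLat, sim$coastLon)

  dates <- as.Date(truth$time, tz = "UTC")
  internest <- !is.na(truth$mode) & truth$mode == "internesting"
  dayIn <- tapply(internest, dates, any)
  inDates <- as.Date(names(dayIn))[dayIn]
  if (length(inDates) == 0) stop("truth contains no inter-nesting phase")

  events <- list()
  nextDate <- inDates[1]
  k <- 0L
  while (nextDate <= max(inDates)) {
    if (any(abs(as.numeric(inDates - nextDate)) <= 2)) {
      k <- k + 1L
      onB <- scenario == "swap" && k %% 2L == 0L
      base <- if (onB) beachB else beachA
      jitterKm <- stats::runif(1, 0, 2)
      events[[k]] <- data.frame(
        turtle_id = "sim01", date = nextDate,
        site_label = if (onB) "beachB" else "beachA",
        lat = base[1] + jitterKm / kmPerDegLat, lon = base[2],
        kind = if (stats::runif(1) < 0.8) "nest" else "false_crawl",
        stringsAsFactors = FALSE
      )
    }
    gap <- max(7, round(stats::rnorm(1, sim$renestIntervalDays, sim$renestIntervalSd)))
    nextDate <- nextDate + gap
  }
  do.call(rbind, events)
}

#' Simulate threat layers
#'
#' Platform point table (some with removal dates) and trawl-effort zones: a
#' set of latitude bands over the shelf, each carrying an effort-days value
#' drawn to cover the four reported effort bands.
#'
#' @param sim a `simConfig()`.
#' @param nPlatforms number of platforms scattered over the shelf.
#' @return list with `platforms` (data.frame) and `zones` (data.frame of
#'   latitude-band zones: lat_min, lat_max, lon_min, lon_max, effort_days).
#' @export
simulateThreats <- function(sim = simConfig(), nPlatforms = 60) {
  set.seed(sim$seed + 2L)
  kmPerDegLon <- (2 * pi * EARTH_RADIUS_KM / 360) * cos(sim$beachLat * pi / 180)
  lon <- sim$coastLon - stats::runif(nPlatforms, 2, sim$shelfWidthKm - 2) / kmPerDegLon
  lat <- stats::runif(nPlatforms, sim$beachLat - 1.5, sim$beachLat + 3)
  removed <- stats::runif(nPlatforms) < 0.2
  platforms <- data.frame(
    platform_id = sprintf("P%03d", seq_len(nPlatforms)),
    lat = lat, lon = lon,
    removal_date = ifelse(removed, "2010-01-01", ""),
    stringsAsFactors = FALSE
  )
  platforms$active <- !removed
  edges <- seq(sim$beachLat - 2, sim$beachLat + 4, length.out = 5)
  zones <- data.frame(
    zone_id = sprintf("Z%d", 1:4),
    lat_min = edges[1:4], lat_max = edges[2:5],
    lon_min = sim$coastLon - (sim$shelfWidthKm + 50) / kmPerDegLon,
    lon_max = sim$coastLon,
    effort_days = c(4, 800, 2000, 4500)
  )
  list(platforms = platforms, zones = zones)
}

#' Load a packaged printed-table fixture
#'
#' Numeric fixtures of the study's three summary tables: `"table1"` (tracking
#' and emergence summaries, 40 rows), `"table2"` (kernel home-range results,
#' 10 rows), `"table3"` (between-centroid distances, 11 rows). Values are
#' carried exactly as printed; nothing is recomputed.
#'
#' @param name fixture name.
#' @return data.frame.
#' @export
loadFixture <- function(name) {
  files <- c(
    table1 = "table1_tracking.csv",
    table2 = "table2_kde.csv",
    table3 = "table3_centroids.csv"
  )
  if (!name %in% names(files)) {
    stop(
      "unknown fixture '", name, "'; available: ",
      paste(names(files), collapse = ", ")
    )
  }
  path <- system.file("extdata", files[[name]], package = "internest")
  if (path == "") stop("fixture file missing from installation")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c(table1 = 40L, table2 = 10L, table3 = 11L)
  stopifnot(nrow(df) == expected[[name]])
  df
}
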