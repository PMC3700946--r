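# Occupancy grid, turtle-days, the Poisson log-link model of grid-cell use,
# and threat-overlap scoring (trawl-effort zones, platform buffers).

#' Build the occupancy grid over shelf water
#'
#' Axis-aligned square cells in a local equal-area frame spanning the given
#' extent; cells whose centre bathymetry falls outside (-200, 0) — land or
#' oceanic water — are excluded.
#'
#' @param latRange,lonRange extent in degrees.
#' @param grid a `bathygrid`.
#' @param cellKm cell edge (km), default 10.
#' @param cutoff neritic cutoff (m).
#' @return object of class `occupancygrid`: data.frame `cells` (cell_id,
#'   center lat/lon, x/y km, depth_m) plus the `eaframe` and cell size.
#' @export
buildGrid <- function(latRange, lonRange, grid, cellKm = 10, cutoff = -200) {
  frame <- equalAreaFrame(mean(latRange), mean(lonRange))
  corners <- frame$forward(
    rep(latRange, each = 2),
    rep(lonRange, times = 2)
  )
  xs <- seq(min(corners$x), max(corners$x), by = cellKm)
  ys <- seq(min(corners$y), max(corners$y), by = cellKm)
  centers <- expand.grid(x = xs + cellKm / 2, y = ys + cellKm / 2)
  ll <- frame$inverse(centers$x, centers$y)
  inExtent <- ll$lon >= grid$xll & ll$lon < grid$xll + grid$ncol * grid$cellsize &
    ll$lat >= grid$yll & ll$lat < grid$yll + grid$nrow * grid$cellsize
  depth <- rep(NA_real_, nrow(centers))
  depth[inExtent] <- depthAt(grid, ll$lat[inExtent], ll$lon[inExtent])
  keep <- !is.na(depth) & depth < 0 & depth > cutoff
  if (!any(keep)) stop("grid extent contains no shelf-water cells")
  cells <- data.frame(
    cell_id = seq_len(sum(keep)),
    x = centers$x[keep], y = centers$y[keep],
    lat = ll$lat[keep], lon = ll$lon[keep],
    depth_m = depth[keep]
  )
  structure(
    list(cells = cells, frame = frame, cellKm = cellKm),
    class = "occupancygrid"
  )
}

#' @export
print.occupancygrid <- function(x, ...) {
  cat(sprintf(
    "occupancy grid: %d shelf-water cells of %g x %g km\n",
    nrow(x$cells), x$cellKm, x$cellKm
  ))
  invisible(x)
}

cellIndexOf <- function(og, lat, lon) {
  xy <- og$frame$forward(lat, lon)
  # match to nearest cell centre within half a cell edge (Chebyshev)
  idx <- integer(length(lat))
  for (i in seq_along(lat)) {
    dx <- abs(og$cells$x - xy$x[i])
    dy <- abs(og$cells$y - xy$y[i])
    hit <- which(dx <= og$cellKm / 2 & dy <= og$cellKm / 2)
    idx[i] <- if (length(hit) >= 1) hit[1] else NA_integer_
  }
  idx
}

#' Turtle-days per grid cell
#'
#' A turtle-day is one calendar (UTC) day on which a given turtle has at
#' least one fix in a given cell; a turtle visiting two cells on one day
#' contributes one day to each. Cell totals sum the per-turtle counts.
#'
#' @param track an `argostrack` (all turtles, filtered).
#' @param og an `occupancygrid`.
#' @return the `occupancygrid` with a `turtle_days` column added to `cells`,
#'   and `visits` (distinct turtle-date-cell triples).
#' @export
turtleDays <- function(track, og) {
  stopifnot(inherits(og, "occupancygrid"))
  dates <- as.Date(track$timestamp, tz = "UTC")
  cellIdx <- cellIndexOf(og, track$lat, track$lon)
  keep <- !is.na(cellIdx)
  visits <- unique(data.frame(
    turtle_id = track$turtle_id[keep],
    date = dates[keep],
    cell = cellIdx[keep]
  ))
  counts <- table(factor(visits$cell, levels = seq_len(nrow(og$cells))))
  og$cells$turtle_days <- as.integer(counts)
  og$visits <- visits
  og
}

#' Poisson log-link model of turtle-days
#'
#' Fits turtle_days ~ covariates with a Poisson family and log link by
#' iteratively reweighted least squares, and reports Wald chi-square
#' statistics per covariate at alpha = 0.05.
#'
#' @param cells data.frame with a `turtle_days` column and covariate columns.
#' @param covariates character vector of covariate column names; empty for an
#'   intercept-only model.
#' @return list: `fit` (the glm object), `coefficients` data.frame (estimate,
#'   se, chisq, p, significant).
#' @export
glmTurtleDays <- function(cells, covariates = c("depth_m", "dist_tagging_km")) {
  stopifnot("turtle_days" %in% names(cells))
  miss <- setdiff(covariates, names(cells))
  if (length(miss) > 0) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (nrow(cells) < 10) stop("need >= 10 cells")
  for (cv in covariates) {
    if (!all(is.finite(cells[[cv]]))) stop("non-finite values in covariate ", cv)
  }
  form <- if (length(covariates) == 0) {
    turtle_days ~ 1
  } else {
    stats::as.formula(paste("turtle_days ~", paste(covariates, collapse = " + ")))
  }
  fit <- stats::glm(form, family = stats::poisson(link = "log"), data = cells,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  )
  if (!fit$converged) stop("IRLS did not converge in 100 iterations")
  sm <- summary(fit)$coefficients
  chisq <- (sm[, "Estimate"] / sm[, "Std. Error"])^2
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(
    fit = fit,
    coefficients = data.frame(
      term = rownames(sm),
      estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
      chisq = chisq, p = p, significant = p < 0.05,
      row.names = NULL
    )
  )
}

#' Count active platforms within a buffer
#'
#' Platforms with a past removal date are excluded; the buffer boundary is
#' inclusive.
#'
#' @param lat,lon centroid coordinates.
#' @param platforms data.frame from [readPlatformCsv()] (or with an `active`
#'   logical column).
#' @param rKm buffer radius (km), default 10.
#' @return integer count (vectorised over centroids).
#' @export
platformsWithinBuffer <- function(lat, lon, platforms, rKm = 10) {
  act <- platforms[platforms$active, , drop = FALSE]
  vapply(seq_along(lat), function(i) {
    if (nrow(act) == 0) {
      return(0L)
    }
    sum(haversineKm(lat[i], lon[i], act$lat, act$lon) <= rKm)
  }, integer(1))
}

TRAWL_BANDS <- data.frame(
  lo = c(4, 5, 1501, 3001),
  hi = c(4, 1500, 3000, 7000),
  label = c("4", "5-1500", "1501-3000", "3001-7000"),
  stringsAsFactors = FALSE
)

#' Trawl-effort category at a centroid
#'
#' Looks up the effort-days of the zone containing the centroid and assigns
#' the reported effort band (closed intervals: 1500 days falls in "5-1500",
#' 1501 in "1501-3000").
#'
#' @param lat,lon centroid coordinates.
#' @param zones data.frame of rectangular zones (lat_min, lat_max, lon_min,
#'   lon_max, effort_days) partitioning the water extent.
#' @return data.frame with `trawl_days` (NA when no zone contains the
#'   centroid) and `band`.
#' @export
trawlCategory <- function(lat, lon, zones) {
  days <- rep(NA_real_, length(lat))
  for (i in seq_along(lat)) {
    hit <- which(lat[i] >= zones$lat_min & lat[i] < zones$lat_max &
      lon[i] >= zones$lon_min & lon[i] < zones$lon_max)
    if (length(hit) >= 1) days[i] <- zones$effort_days[hit[1]]
  }
  band <- vapply(days, function(d) {
    if (is.na(d)) {
      return(NA_character_)
    }
    hit <- which(d >= TRAWL_BANDS$lo & d <= TRAWL_BANDS$hi)
    if (length(hit) == 0) NA_character_ else TRAWL_BANDS$label[hit[1]]
  }, character(1))
  data.frame(trawl_days = days, band = band, stringsAsFactors = FALSE)
}
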