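# Track cleaning: location-class rejection, swim-speed limit, land/depth
# masking, and reduction to mean daily locations. The pipeline default is the
# chain lc -> speed -> mask, which is idempotent.

newFilterReport <- function(input, retained, drops) {
  rep <- list(input = input, retained = retained, dropped = drops)
  stopifnot(sum(unlist(drops)) + retained == input)
  class(rep) <- "filterreport"
  rep
}

#' @export
print.filterreport <- function(x, ...) {
  cat(sprintf(
    "filter report: %d in, %d retained (%s)\n", x$input, x$retained,
    paste(sprintf("%s=%d", names(x$dropped), unlist(x$dropped)), collapse = ", ")
  ))
  invisible(x)
}

#' Reject LC Z fixes
#'
#' Argos class Z positions carry no error estimate and are discarded.
#' @param track an `argostrack` data.frame (any number of turtles).
#' @return list with elements `track` (order preserved) and `report`.
#' @export
dropLcZ <- function(track) {
  keep <- track$lc != "Z"
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(
    track = out,
    report = newFilterReport(nrow(track), nrow(out), list(lc_z = sum(!keep)))
  )
}

#' Swim-speed filter
#'
#' Forward sweep per turtle: the first fix is always retained; each later fix
#' is dropped when the great-circle speed from the last retained fix exceeds
#' `vmax`. A fix at zero time gap from the last retained fix but a different
#' position is dropped and logged. All consecutive retained speeds are
#' therefore <= vmax, and a second pass changes nothing.
#'
#' @param track an `argostrack` with strictly increasing timestamps per turtle.
#' @param vmax speed limit in km/h (default 5, loggerhead swim-speed cap).
#' @return list with `track` and `report`.
#' @export
speedFilter <- function(track, vmax = 5) {
  stopifnot(vmax > 0)
  keepAll <- logical(nrow(track))
  zeroGap <- 0L
  for (id in unique(track$turtle_id)) {
    idx <- which(track$turtle_id == id)
    if (length(idx) == 0) next
    lastKept <- idx[1]
    keepAll[lastKept] <- TRUE
    for (i in idx[-1]) {
      dt <- as.numeric(difftime(track$timestamp[i], track$timestamp[lastKept],
        units = "hours"
      ))
      dKm <- haversineKm(
        track$lat[lastKept], track$lon[lastKept],
        track$lat[i], track$lon[i]
      )
      if (dt <= 0) {
        if (dKm > 0) zeroGap <- zeroGap + 1L
        next
      }
      if (dKm / dt <= vmax) {
        keepAll[i] <- TRUE
        lastKept <- i
      }
    }
  }
  out <- track[keepAll, , drop = FALSE]
  rownames(out) <- NULL
  nDrop <- nrow(track) - nrow(out)
  list(
    track = out,
    report = newFilterReport(nrow(track), nrow(out),
      list(speed = nDrop - zeroGap, zero_gap = zeroGap)
    )
  )
}

#' Mask land and oceanic fixes
#'
#' Retains fixes whose bathymetry lies in [cutoff, 0): on-shelf, in water.
#' The lower bound is closed — a fix at exactly the cutoff depth is kept.
#'
#' @param track an `argostrack`.
#' @param grid a `bathygrid`.
#' @param cutoff neritic depth cutoff in metres (default -200).
#' @param outside how to treat fixes outside the grid extent: `"drop"` (logged)
#'   or `"error"`.
#' @return list with `track` and `report` (counts for land, deep, off-grid).
#' @export
maskLandAndDeep <- function(track, grid, cutoff = -200, outside = c("drop", "error")) {
  outside <- match.arg(outside)
  stopifnot(cutoff < 0)
  inGrid <- track$lon >= grid$xll & track$lon < grid$xll + grid$ncol * grid$cellsize &
    track$lat >= grid$yll & track$lat < grid$yll + grid$nrow * grid$cellsize
  if (any(!inGrid) && outside == "error") {
    i <- which(!inGrid)[1]
    stop(sprintf("fix (%g, %g) outside bathymetry extent", track$lat[i], track$lon[i]))
  }
  depth <- rep(NA_real_, nrow(track))
  if (any(inGrid)) {
    depth[inGrid] <- depthAt(grid, track$lat[inGrid], track$lon[inGrid])
  }
  land <- inGrid & !is.na(depth) & depth >= 0
  deep <- inGrid & !is.na(depth) & depth < cutoff
  keep <- inGrid & !is.na(depth) & depth >= cutoff & depth < 0
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(
    track = out,
    report = newFilterReport(nrow(track), nrow(out), list(
      land = sum(land), deep = sum(deep),
      off_grid = sum(!inGrid) + sum(inGrid & is.na(depth))
    ))
  )
}

#' Full filter chain
#'
#' lc -> speed -> land/depth, the pipeline default order.
#' @inheritParams maskLandAndDeep
#' @param vmax speed limit km/h.
#' @return list with `track` and the three stage `reports`.
#' @export
filterTrack <- function(track, grid, vmax = 5, cutoff = -200) {
  a <- dropLcZ(track)
  b <- speedFilter(a$track, vmax)
  c <- maskLandAndDeep(b$track, grid, cutoff)
  list(track = c$track, reports = list(lc = a$report, speed = b$report, mask = c$report))
}

#' Mean daily locations
#'
#' One location per turtle per UTC date: the arithmetic mean of that date's
#' fix latitudes and longitudes (the study region spans no antimeridian, which
#' is asserted). Reduces serial autocorrelation ahead of kernel estimation.
#'
#' @param track an `argostrack` (already filtered).
#' @return data.frame with columns turtle_id, date, lat, lon, n_fixes.
#' @export
meanDailyLocations <- function(track) {
  if (nrow(track) == 0) {
    return(data.frame(
      turtle_id = character(), date = as.Date(character()),
      lat = numeric(), lon = numeric(), n_fixes = integer()
    ))
  }
  if (diff(range(track$lon)) > 180) {
    stop("track spans the antimeridian; arithmetic longitude averaging invalid")
  }
  date <- as.Date(track$timestamp, tz = "UTC")
  key <- paste(track$turtle_id, date)
  agg <- lapply(split(seq_len(nrow(track)), key), function(ii) {
    data.frame(
      turtle_id = track$turtle_id[ii[1]], date = date[ii[1]],
      lat = mean(track$lat[ii]), lon = mean(track$lon[ii]),
      n_fixes = length(ii)
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$turtle_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}
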