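# Site-fidelity and emergence statistics: the Monte Carlo random-walk test of
# in-water site fidelity, the 5-km nest-site-fidelity rule, successive
# emergence distances and intervals, total distance moved, and the summary
# helpers used against the printed-table fixtures.

#' Monte Carlo random-walk site-fidelity test
#'
#' Tests whether a track is more spatially constrained than random walks with
#' the same step lengths. The statistic is the mean squared displacement (MSD)
#' from the first point, computed in a local equal-area kilometre frame. The
#' frame already removes the latitude/longitude scale anisotropy that
#' historically motivated standardising the coordinates; standardising each
#' axis to unit variance on top of it would blind the statistic to the
#' elongation that distinguishes directed from resident movement.
#' Each of `nRep` null walks keeps the observed step-length sequence, draws
#' headings uniformly on [0, 2 pi), starts at the observed start, and stays
#' within the water domain (0 to -200 m bathymetry): a step leaving the
#' domain is re-drawn up to 100 times, then reflected back about the previous
#' point. The track passes when its MSD is below at least 95% of the null
#' MSDs.
#'
#' @param lat,lon track points (>= 10), all within the water domain.
#' @param grid a `bathygrid` bounding the walks.
#' @param nRep number of random walks (default 100).
#' @param seed RNG seed; the same seed reproduces the null exactly.
#' @param cutoff neritic cutoff in metres.
#' @return object of class `fidelitytest`: `observed_msd`, `null_msd` (length
#'   `nRep`), `prop_null_exceeding`, `passes`, `seed`.
#' @export
siteFidelityTest <- function(lat, lon, grid, nRep = 100, seed = 1, cutoff = -200) {
  n <- length(lat)
  stopifnot(length(lon) == n)
  if (n < 10) stop("need >= 10 points for the site-fidelity test")
  d0 <- depthAt(grid, lat, lon)
  if (is.na(d0[1]) || d0[1] >= 0 || d0[1] < cutoff) {
    stop("start point outside the 0 to -200 m water domain")
  }
  if (!any(!is.na(grid$values) & grid$values < 0 & grid$values >= cutoff)) {
    stop("domain contains no water cells")
  }
  frame <- frameForPoints(lat, lon)
  xy <- frame$forward(lat, lon)
  if (stats::sd(xy$x) < 1e-9 && stats::sd(xy$y) < 1e-9) {
    stop("degenerate track spread")
  }

  msdOf <- function(x, y) mean((x - x[1])^2 + (y - y[1])^2)
  observed <- msdOf(xy$x, xy$y)

  steps <- sqrt(diff(xy$x)^2 + diff(xy$y)^2)
  inDomain <- function(x, y) {
    ll <- frame$inverse(x, y)
    if (ll$lon < grid$xll || ll$lon >= grid$xll + grid$ncol * grid$cellsize ||
      ll$lat < grid$yll || ll$lat >= grid$yll + grid$nrow * grid$cellsize) {
      return(FALSE)
    }
    d <- depthAt(grid, ll$lat, ll$lon)
    !is.na(d) && d < 0 && d >= cutoff
  }

  set.seed(seed)
  nullMsd <- numeric(nRep)
  for (r in seq_len(nRep)) {
    wx <- numeric(n)
    wy <- numeric(n)
    wx[1] <- xy$x[1]
    wy[1] <- xy$y[1]
    for (k in seq_len(n - 1)) {
      placed <- FALSE
      for (try in 1:100) {
        a <- stats::runif(1, 0, 2 * pi)
        cx <- wx[k] + steps[k] * cos(a)
        cy <- wy[k] + steps[k] * sin(a)
        if (inDomain(cx, cy)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # reflect the last attempt back about the previous point
        cx <- wx[k] - steps[k] * cos(a)
        cy <- wy[k] - steps[k] * sin(a)
      }
      wx[k + 1] <- cx
      wy[k + 1] <- cy
    }
    nullMsd[r] <- msdOf(wx, wy)
  }
  prop <- mean(nullMsd > observed)
  structure(
    list(
      observed_msd = observed, null_msd = nullMsd,
      prop_null_exceeding = prop, passes = prop >= 0.95, seed = seed
    ),
    class = "fidelitytest"
  )
}

#' @export
print.fidelitytest <- function(x, ...) {
  cat(sprintf(
    "site-fidelity test: observed MSD %.3f, %.0f%% of %d null walks more dispersed -> %s\n",
    x$observed_msd, 100 * x$prop_null_exceeding, length(x$null_msd),
    if (x$passes) "PASS (site fidelity)" else "no fidelity"
  ))
  invisible(x)
}

#' Nest-site-fidelity classification
#'
#' Successive emergences within 5 km of each other indicate nest-site
#' fidelity; the 5.0-km boundary is inclusive.
#'
#' @param dKm distance between successive emergences (km, >= 0).
#' @param radiusKm classification radius (default 5).
#' @return character: "fidelity" or "none" (vectorised).
#' @export
nestSiteFidelity <- function(dKm, radiusKm = 5) {
  if (any(!is.finite(dKm)) || any(dKm < 0)) stop("distances must be finite and non-negative")
  ifelse(dKm <= radiusKm, "fidelity", "none")
}

#' Emergence statistics
#'
#' Per-turtle successive-pair great-circle distances and day intervals, the
#' per-turtle mean distance, and the pooled distance-weighted mean:
#' sum(mean_i * n_i) / sum(n_i) over turtles.
#'
#' @param emergences data.frame (turtle_id, date, lat, lon, ...), date-sorted
#'   per turtle (as from [readEmergenceCsv()]).
#' @return list: `perTurtle` data.frame (turtle_id, n_emergences, n_distances,
#'   mean_distance_km, mean_interval_d), `pooled` list (n_distances,
#'   weighted_mean_km, sd_km over all pairwise distances).
#' @export
emergenceStats <- function(emergences) {
  per <- lapply(split(emergences, emergences$turtle_id), function(e) {
    e <- e[order(e$date), , drop = FALSE]
    k <- nrow(e)
    if (k < 2) {
      return(data.frame(
        turtle_id = e$turtle_id[1], n_emergences = k, n_distances = 0L,
        mean_distance_km = NA_real_, mean_interval_d = NA_real_
      ))
    }
    d <- haversineKm(e$lat[-k], e$lon[-k], e$lat[-1], e$lon[-1])
    iv <- as.numeric(diff(e$date))
    data.frame(
      turtle_id = e$turtle_id[1], n_emergences = k, n_distances = k - 1L,
      mean_distance_km = mean(d), mean_interval_d = mean(iv)
    )
  })
  perTurtle <- do.call(rbind, per)
  rownames(perTurtle) <- NULL
  pooled <- pooledEmergenceMean(
    perTurtle$mean_distance_km,
    perTurtle$n_distances
  )
  list(perTurtle = perTurtle, pooled = pooled)
}

#' Pooled distance-weighted emergence-distance mean
#'
#' @param meanKm per-turtle mean successive-emergence distances.
#' @param n per-turtle distance counts.
#' @return list: `n_distances`, `weighted_mean_km`.
#' @export
pooledEmergenceMean <- function(meanKm, n) {
  keep <- !is.na(meanKm) & n > 0
  list(
    n_distances = sum(n[keep]),
    weighted_mean_km = sum(meanKm[keep] * n[keep]) / sum(n[keep])
  )
}

#' Total distance moved
#'
#' Sum of successive great-circle distances between filtered fixes from the
#' period start to the period end, and the per-day rate (TDM / period length
#' in days).
#'
#' @param track single-turtle `argostrack` (filtered).
#' @param start,end period bounds (Date); fixes with UTC dates in
#'   [start, end] are used.
#' @return list: `tdm_km`, `days`, `tdm_per_day`, `n_fixes`.
#' @export
totalDistanceMoved <- function(track, start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (end < start) stop("empty period: end precedes start")
  dates <- as.Date(track$timestamp, tz = "UTC")
  sub <- track[dates >= start & dates <= end, , drop = FALSE]
  if (nrow(sub) < 2) stop("fewer than 2 fixes in the period")
  n <- nrow(sub)
  tdm <- sum(haversineKm(sub$lat[-n], sub$lon[-n], sub$lat[-1], sub$lon[-1]))
  days <- as.integer(end - start) + 1L
  list(tdm_km = tdm, days = days, tdm_per_day = tdm / days, n_fixes = n)
}

#' Column summary against printed precision
#'
#' Mean, sample SD (n-1 denominator), range and total of a numeric column,
#' with values rounded half-up for comparison with printed tables. A
#' single-element column has its SD flagged undefined (NA).
#'
#' @param x numeric vector (NAs dropped).
#' @param digits decimal places of the printed values.
#' @return list: `n`, `mean`, `sd`, `min`, `max`, `total` (rounded), and the
#'   unrounded `mean_raw`, `sd_raw`, `total_raw`.
#' @export
summarizeColumn <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty column")
  m <- mean(x)
  s <- if (length(x) >= 2) stats::sd(x) else NA_real_
  list(
    n = length(x),
    mean = roundHalfUp(m, digits),
    sd = if (is.na(s)) NA_real_ else roundHalfUp(s, digits),
    min = roundHalfUp(min(x), digits),
    max = roundHalfUp(max(x), digits),
    total = roundHalfUp(sum(x), digits),
    mean_raw = m, sd_raw = s, total_raw = sum(x),
    sd_undefined = is.na(s)
  )
}

#' Summaries of the packaged printed-table fixtures
#'
#' Recomputes from the fixture tables the study-level summary statistics:
#' tracking-day and inter-nesting-day totals and means, carapace-length mean,
#' total-distance-moved means, kernel areas, centroid depths and shore
#' distances, occupancy days, between-centroid totals, and the pooled
#' distance-weighted emergence-distance mean.
#'
#' @return named list of [summarizeColumn()] results plus the pooled
#'   emergence mean.
#' @export
summarizeTables <- function() {
  t1 <- loadFixture("table1")
  t2 <- loadFixture("table2")
  t3 <- loadFixture("table3")
  list(
    tracking_days = summarizeColumn(t1$tracking_days),
    ccl = summarizeColumn(t1$ccl_cm),
    internesting_days = summarizeColumn(t1$internesting_days),
    tdm = summarizeColumn(t1$tdm_km),
    tdm_per_day = summarizeColumn(t1$tdm_per_day),
    encounters = summarizeColumn(t1$encounters),
    area50 = summarizeColumn(t2$area50_km2),
    area95 = summarizeColumn(t2$area95_km2),
    centroid_depth = summarizeColumn(t2$centroid_depth_m),
    centroid_to_shore = summarizeColumn(t2$centroid_to_shore_km),
    occupancy_days = summarizeColumn(t2$occupancy_days),
    centroid_totals = summarizeColumn(t3$total_km),
    emergence_pooled = pooledEmergenceMean(t1$mean_distance_km, t1$n_distances)
  )
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation via the exact t transform (wraps
#' [stats::cor.test()]).
#'
#' @param x,y paired finite values, n >= 3.
#' @return list: `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
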