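# Fixed-kernel utilisation distributions with least-squares cross-validation
# bandwidths, probability contours clipped to water, and minimum convex
# polygons. All computations run in a local equal-area frame (km) centred on
# the point set; contours are extracted by marching squares at the density
# threshold whose enclosed mass matches the requested probability level.

#' Least-squares cross-validation bandwidth
#'
#' Minimises the Gaussian-kernel LSCV score over a logarithmic grid of 50
#' candidates spanning [0.05, 2] x the pooled standard deviation. When the
#' axis standard deviations differ by more than 10%, coordinates are rescaled
#' to unit variance, a single bandwidth is chosen, and it is back-scaled per
#' axis.
#'
#' @param x,y point coordinates in the equal-area frame (km); >= 20 points
#'   expected (the pipeline's kernel-eligibility rule).
#' @param nGrid number of candidate bandwidths.
#' @return list: `h` (length-2 per-axis bandwidth, km), `hScaled` (the common
#'   bandwidth on the search scale), `rescaled` (logical), `score` (the LSCV
#'   score at the optimum), `candidates`, `scores`.
#' @export
lscvBandwidth <- function(x, y, nGrid = 50) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 5) stop("too few points for cross-validation")
  sdx <- stats::sd(x)
  sdy <- stats::sd(y)
  if (sdx < 1e-12 && sdy < 1e-12) stop("all points identical; bandwidth undefined")
  if (min(sdx, sdy) < 1e-12) stop("degenerate spread on one axis")
  rescaled <- abs(sdx - sdy) / max(sdx, sdy) > 0.10
  if (rescaled) {
    u <- x / sdx
    v <- y / sdy
    sigma <- 1
  } else {
    u <- x
    v <- y
    sigma <- sqrt((sdx^2 + sdy^2) / 2)
  }
  d2 <- (outer(u, u, "-"))^2 + (outer(v, v, "-"))^2
  off <- d2[upper.tri(d2)] # pairwise squared distances, i < j
  cand <- exp(seq(log(0.05 * sigma), log(2 * sigma), length.out = nGrid))
  scores <- vapply(cand, function(h) lscvScore(off, n, h), numeric(1))
  best <- which.min(scores)
  hs <- cand[best]
  h <- if (rescaled) c(hs * sdx, hs * sdy) else c(hs, hs)
  list(
    h = h, hScaled = hs, rescaled = rescaled, score = scores[best],
    candidates = cand, scores = scores
  )
}

# LSCV score for an isotropic bivariate Gaussian kernel:
#   int fhat^2 - (2/n) sum_i fhat_{-i}(x_i)
# both terms reduce to sums of Gaussians of the pairwise distances.
lscvScore <- function(d2pairs, n, h) {
  intF2 <- (n + 2 * sum(exp(-d2pairs / (4 * h^2)))) / (n^2 * 4 * pi * h^2)
  loo <- 2 * sum(exp(-d2pairs / (2 * h^2))) / (n * (n - 1) * 2 * pi * h^2)
  intF2 - 2 * loo
}

#' Gaussian kernel density on a regular grid
#'
#' @param x,y points (km); `h` per-axis bandwidths.
#' @param pad grid padding beyond the point extent, in multiples of max(h).
#' @param resFactor grid resolution as a fraction of min(h) (<= 1/3 enforced).
#' @return list: `gx`, `gy` (cell-centre coordinate vectors), `z` (density
#'   matrix [ix, iy]), `cell` (cell edge lengths).
#' @export
kdeDensityGrid <- function(x, y, h, pad = 3, resFactor = 1 / 3) {
  stopifnot(length(h) == 2, all(h > 0), resFactor <= 1 / 3 + 1e-12)
  n <- length(x)
  hm <- max(h)
  dx <- min(h) * resFactor
  gx <- seq(min(x) - pad * hm, max(x) + pad * hm, by = dx)
  gy <- seq(min(y) - pad * hm, max(y) + pad * hm, by = dx)
  # separable Gaussian products, accumulated per point
  z <- matrix(0, length(gx), length(gy))
  for (i in seq_len(n)) {
    kx <- stats::dnorm(gx, x[i], h[1])
    ky <- stats::dnorm(gy, y[i], h[2])
    z <- z + outer(kx, ky)
  }
  z <- z / n
  list(gx = gx, gy = gy, z = z, cell = c(dx, dx))
}

# density threshold whose superlevel set carries `level` probability mass
massThreshold <- function(z, cellArea, level) {
  ord <- sort(as.numeric(z), decreasing = TRUE)
  cum <- cumsum(ord) * cellArea
  k <- which(cum >= level)[1]
  if (is.na(k)) {
    return(min(ord))
  }
  ord[k]
}

#' Kernel density probability contours
#'
#' Finds, for each level, the highest-density region containing that
#' probability mass, and extracts its boundary polygons by marching squares.
#'
#' @param x,y points (km, equal-area frame).
#' @param h per-axis bandwidth (km), e.g. from [lscvBandwidth()].
#' @param levels probability masses in (0, 1), default 0.50 and 0.95.
#' @return object of class `kderesult`: per level a list of rings (2-column
#'   km matrices) with `area_km2`, plus `mass` (grid-integrated mass inside
#'   the rings), `grid`, `h`.
#' @export
kdeContours <- function(x, y, h, levels = c(0.50, 0.95)) {
  if (any(levels <= 0 | levels >= 1)) stop("contour levels must lie in (0, 1)")
  grid <- kdeDensityGrid(x, y, h)
  cellArea <- prod(grid$cell)
  total <- sum(grid$z) * cellArea
  if (abs(total - 1) > 1e-3) {
    warning(sprintf("density integrates to %.4f on its grid", total))
  }
  out <- list(levels = list(), grid = grid, h = h)
  for (lv in sort(levels)) {
    thr <- massThreshold(grid$z, cellArea, lv)
    cl <- grDevices::contourLines(grid$gx, grid$gy, grid$z, levels = thr)
    rings <- lapply(cl, function(c1) closeRing(cbind(c1$x, c1$y)))
    mass <- sum(grid$z[grid$z >= thr]) * cellArea
    areas <- vapply(rings, polygonArea, numeric(1))
    out$levels[[sprintf("%.2f", lv)]] <- list(
      level = lv, threshold = thr, rings = rings,
      area_km2 = sum(areas), ring_areas = areas, mass = mass
    )
  }
  class(out) <- "kderesult"
  out
}

#' @export
print.kderesult <- function(x, ...) {
  cat("kernel home range, h =", sprintf("%.3f", x$h), "km\n")
  for (lv in x$levels) {
    cat(sprintf(
      "  %2.0f%%: %d ring(s), %.1f km^2 (grid mass %.3f)\n",
      100 * lv$level, length(lv$rings), lv$area_km2, lv$mass
    ))
  }
  invisible(x)
}

#' Clip polygons to water and compute in-water area
#'
#' Rasterises the rings over the supplied bathymetry and counts cells whose
#' centres are in the polygons and in water (elevation < 0), in the frame the
#' rings live in. Mirrors the convention that any land inside a home-range
#' contour is removed from its area.
#'
#' @param rings list of 2-column ring matrices (km, equal-area frame).
#' @param grid a `bathygrid`.
#' @param frame the `eaframe` mapping the rings to lat/lon.
#' @param cellKm rasterisation cell edge (km).
#' @return list: `area_km2` (in-water area), `total_km2` (unclipped),
#'   `waterFraction`.
#' @export
clipToWater <- function(rings, grid, frame, cellKm = 0.5) {
  if (length(rings) == 0) {
    return(list(area_km2 = 0, total_km2 = 0, waterFraction = NA_real_))
  }
  allv <- do.call(rbind, rings)
  xs <- seq(min(allv[, 1]) - cellKm, max(allv[, 1]) + cellKm, by = cellKm)
  ys <- seq(min(allv[, 2]) - cellKm, max(allv[, 2]) + cellKm, by = cellKm)
  pts <- expand.grid(x = xs, y = ys)
  inside <- pointInPolygon(pts$x, pts$y, rings)
  if (!any(inside)) {
    return(list(area_km2 = 0, total_km2 = 0, waterFraction = NA_real_))
  }
  ll <- frame$inverse(pts$x[inside], pts$y[inside])
  depth <- depthAt(grid, ll$lat, ll$lon)
  water <- !is.na(depth) & depth < 0
  cellArea <- cellKm^2
  list(
    area_km2 = sum(water) * cellArea,
    total_km2 = sum(inside) * cellArea,
    waterFraction = mean(water)
  )
}

#' Minimum convex polygon home range
#'
#' Convex hull of all points (the 100% MCP) with its area and centroid.
#' Degenerate inputs (< 3 distinct points, or collinear) return zero area,
#' the point mean as centroid, and `degenerate = TRUE`.
#'
#' @param x,y points (km, equal-area frame).
#' @return object of class `mcpresult`: `hull` (ring matrix), `area_km2`,
#'   `centroid` (x, y km), `degenerate`, `n`.
#' @export
mcp <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 1)
  hull <- if (n >= 3) convexHull(x, y) else cbind(x, y)
  area <- if (nrow(hull) >= 3) polygonArea(hull) else 0
  degenerate <- area <= 1e-12
  centroid <- if (degenerate) c(mean(x), mean(y)) else polygonCentroid(hull)
  structure(
    list(
      hull = hull, area_km2 = area, centroid = centroid,
      degenerate = degenerate, n = n
    ),
    class = "mcpresult"
  )
}

#' @export
print.mcpresult <- function(x, ...) {
  cat(sprintf(
    "MCP of %d points: %.2f km^2, centroid (%.2f, %.2f)%s\n",
    x$n, x$area_km2, x$centroid[1], x$centroid[2],
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Centroid of the largest core-use activity centre
#'
#' When the 50% contour splits into several activity centres, the centroid of
#' the largest (by area) is used; an exact tie is broken by the westernmost
#' centroid.
#'
#' @param kde a `kderesult` containing a 0.50 level.
#' @return length-2 (x, y) centroid in the frame (km).
#' @export
centroidOfCore <- function(kde) {
  stopifnot(inherits(kde, "kderesult"))
  core <- kde$levels[["0.50"]]
  if (is.null(core) || length(core$rings) == 0) stop("no 50% contour present")
  areas <- core$ring_areas
  cents <- t(vapply(core$rings, polygonCentroid, numeric(2)))
  best <- which(areas == max(areas))
  if (length(best) > 1) best <- best[which.min(cents[best, 1])]
  cents[best, ]
}
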