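# Planar polygon primitives used by the home-range and grid stages. Rings are
# 2-column matrices (x, y) in the local equal-area frame (km); the last vertex
# need not repeat the first.

closeRing <- function(ring) {
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE))) {
    ring <- rbind(ring, ring[1, ])
  }
  ring
}

#' Signed and absolute polygon area (shoelace)
#' @param ring 2-column matrix of vertices (km).
#' @return area in km^2 (absolute value).
#' @export
polygonArea <- function(ring) {
  ring <- closeRing(as.matrix(ring))
  x <- ring[, 1]
  y <- ring[, 2]
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Polygon centroid (area-weighted)
#' @param ring 2-column matrix of vertices (km).
#' @return length-2 numeric (x, y). Degenerate rings fall back to vertex mean.
#' @export
polygonCentroid <- function(ring) {
  ring <- closeRing(as.matrix(ring))
  x <- ring[, 1]
  y <- ring[, 2]
  n <- length(x)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    return(c(mean(x[-n]), mean(y[-n])))
  }
  c(sum((x[-n] + x[-1]) * cr), sum((y[-n] + y[-1]) * cr)) / (6 * a)
}

#' Points in polygon (even-odd rule)
#'
#' Ray-casting test. With several rings the crossings are combined, so rings
#' nested inside others act as holes.
#'
#' @param px,py query point coordinates.
#' @param rings a single 2-column matrix or a list of them.
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    ring <- as.matrix(ring)
    n <- nrow(ring)
    if (isTRUE(all.equal(ring[1, ], ring[n, ], check.attributes = FALSE))) {
      ring <- ring[-n, , drop = FALSE]
      n <- n - 1L
    }
    xs <- ring[, 1]
    ys <- ring[, 2]
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      x1 <- xs[k]; y1 <- ys[k]
      x2 <- xs[j[k]]; y2 <- ys[j[k]]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Convex hull of points
#'
#' Wrapper around [grDevices::chull()] returning vertices in counter-clockwise
#' order.
#' @param x,y point coordinates (km).
#' @return 2-column matrix of hull vertices.
#' @export
convexHull <- function(x, y) {
  idx <- grDevices::chull(x, y)
  ring <- cbind(x[idx], y[idx])
  # chull returns clockwise; reverse for CCW orientation
  ring[rev(seq_len(nrow(ring))), , drop = FALSE]
}
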