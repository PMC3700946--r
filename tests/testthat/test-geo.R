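test_that("haversine matches the analytic one-degree arc and is symmetric", {
  expect_equal(haversineKm(0, 0, 0, 0), 0)
  # one degree of arc on a sphere of radius 6371.0088 km
  expect_equal(haversineKm(0, 0, 0, 1), 2 * pi * 6371.0088 / 360, tolerance = 1e-9)
  expect_equal(round(haversineKm(0, 0, 0, 1), 3), 111.195)

  set.seed(11)
  a <- cbind(runif(100, -80, 80), runif(100, -170, 170))
  b <- cbind(runif(100, -80, 80), runif(100, -170, 170))
  expect_equal(
    haversineKm(a[, 1], a[, 2], b[, 1], b[, 2]),
    haversineKm(b[, 1], b[, 2], a[, 1], a[, 2])
  )
  expect_error(haversineKm(NA, 0, 0, 0), "non-finite")
  expect_error(haversineKm(95, 0, 0, 0), "latitude")
})

test_that("haversine agrees with the spherical law of cosines and geosphere", {
  slc <- function(lat1, lon1, lat2, lon2) {
    p1 <- lat1 * pi / 180
    p2 <- lat2 * pi / 180
    dl <- (lon2 - lon1) * pi / 180
    6371.0088 * acos(pmin(1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)))
  }
  set.seed(21)
  lat1 <- runif(50, -60, 60)
  lon1 <- runif(50, -170, 170)
  lat2 <- runif(50, -60, 60)
  lon2 <- runif(50, -170, 170)
  expect_equal(haversineKm(lat1, lon1, lat2, lon2), slc(lat1, lon1, lat2, lon2),
    tolerance = 1e-6
  )
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371008.8) / 1000
  expect_equal(haversineKm(lat1, lon1, lat2, lon2), ref, tolerance = 1e-9)
})

test_that("haversine satisfies the triangle inequality", {
  set.seed(31)
  for (i in 1:100) {
    p <- matrix(c(runif(3, -80, 80), runif(3, -170, 170)), ncol = 2)
    ab <- haversineKm(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    bc <- haversineKm(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    ac <- haversineKm(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(ac, ab + bc + 1e-9)
  }
})

test_that("equal-area frame inverts exactly and preserves equatorial cell area", {
  fr <- equalAreaFrame(29, -88)
  set.seed(41)
  lat <- runif(200, 24, 34)
  lon <- runif(200, -93, -83)
  xy <- fr$forward(lat, lon)
  back <- fr$inverse(xy$x, xy$y)
  expect_equal(back$lat, lat, tolerance = 1e-9)
  expect_equal(back$lon, lon, tolerance = 1e-9)

  # 1x1 degree cell at the frame centre on the equator: area within 0.5%
  fr0 <- equalAreaFrame(0, 0)
  corners <- fr0$forward(c(-0.5, -0.5, 0.5, 0.5), c(-0.5, 0.5, 0.5, -0.5))
  area <- polygonArea(cbind(corners$x, corners$y))
  expect_equal(area, 111.195^2, tolerance = 0.005)
})

test_that("depth lookup uses the containing cell with a north-east tie rule", {
  g <- rampGrid()
  # centre of the cell containing (-0.155, 0.05): value = 1000 * lon_centre
  got <- depthAt(g, 0.05, -0.155)
  lonCentre <- g$xll + (floor((-0.155 - g$xll) / g$cellsize) + 0.5) * g$cellsize
  expect_equal(got, 1000 * lonCentre)
  expect_equal(depthAt(g, 0.05, 0.05), 2) # land

  # exact boundary resolves north-east (exactly representable grid)
  gq <- bathymetryGrid(0, 0, 0.25, matrix(1:64, 8, 8))
  expect_equal(depthAt(gq, 0.75, 1.25), gq$values[4, 6])

  expect_error(depthAt(g, 5, 0), "outside grid extent")
})

test_that("depth matches the analytic ramp within one cell", {
  g <- rampGrid()
  set.seed(51)
  lon <- runif(100, -0.45, -0.05)
  lat <- runif(100, -0.15, 0.15)
  expect_true(all(abs(depthAt(g, lat, lon) - 1000 * lon) <= 1000 * g$cellsize))
})

test_that("distance to shore matches the analytic coast and a brute-force scan", {
  g <- rampGrid(lonRange = c(-1, 0.2), latRange = c(-0.3, 0.3))
  # point half a degree offshore on the equator: ~55.6 km to the lon=0 coast
  d <- distanceToShoreKm(g, 0, -0.5)
  expect_equal(d, 111.195 / 2, tolerance = 111.195 * g$cellsize / (111.195 / 2))
  expect_equal(distanceToShoreKm(g, 0, 0.1), 0) # on land

  # brute-force oracle on a coarse 50x50 grid
  set.seed(61)
  vals <- matrix(runif(2500, -50, 10), 50, 50)
  gg <- bathymetryGrid(-1, -1, 0.04, vals)
  cc <- gridCellCenters(gg)
  land <- which(vals >= 0, arr.ind = TRUE)
  pts <- cbind(runif(20, -0.9, 0.9), runif(20, -0.9, 0.9))
  for (i in seq_len(nrow(pts))) {
    exhaustive <- min(haversineKm(
      pts[i, 1], pts[i, 2],
      cc$lat[land[, 1]], cc$lon[land[, 2]]
    ))
    got <- distanceToShoreKm(gg, pts[i, 1], pts[i, 2])
    d0 <- depthAt(gg, pts[i, 1], pts[i, 2])
    if (d0 >= 0) exhaustive <- 0
    expect_equal(got, exhaustive)
  }

  gWater <- bathymetryGrid(0, 0, 0.1, matrix(-5, 4, 4))
  expect_error(distanceToShoreKm(gWater, 0.2, 0.2), "no land")
})

test_that("ESRI ASCII grids round-trip", {
  g <- rampGrid()
  path <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(g, path)
  g2 <- readAsciiGrid(path)
  expect_equal(g2$values, g$values, ignore_attr = TRUE)
  expect_equal(g2$xll, g$xll)
  expect_equal(g2$cellsize, g$cellsize)

  # nodata cells survive
  g$values[3, 4] <- NA
  writeAsciiGrid(g, path)
  expect_true(is.na(readAsciiGrid(path)$values[3, 4]))
})
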