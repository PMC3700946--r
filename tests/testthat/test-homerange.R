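test_that("LSCV bandwidth is near the reference rule and is a local minimiser", {
  set.seed(111)
  x <- rnorm(500)
  y <- rnorm(500)
  bw <- lscvBandwidth(x, y)
  ref <- 500^(-1 / 6) # n^(-1/6) * sigma with sigma = 1
  expect_gt(bw$hScaled, ref / 2)
  expect_lt(bw$hScaled, ref * 2)

  # minimiser property against halved and doubled bandwidths
  d2 <- (outer(x, x, "-"))^2 + (outer(y, y, "-"))^2
  off <- d2[upper.tri(d2)]
  s <- function(h) internest:::lscvScore(off, 500, h)
  expect_lte(bw$score, s(bw$hScaled / 2))
  expect_lte(bw$score, s(bw$hScaled * 2))
})

test_that("LSCV bandwidth is scale-equivariant and rescales unequal axes", {
  set.seed(121)
  x <- rnorm(200)
  y <- rnorm(200)
  b1 <- lscvBandwidth(x, y)
  b2 <- lscvBandwidth(3 * x, 3 * y)
  expect_equal(b2$h, 3 * b1$h, tolerance = 1e-9)

  b3 <- lscvBandwidth(x, 5 * y)
  expect_true(b3$rescaled)
  expect_equal(b3$h[2] / b3$h[1], sd(5 * y) / sd(x), tolerance = 1e-9)

  expect_error(lscvBandwidth(rep(1, 30), rep(2, 30)), "identical|degenerate")
})

test_that("50% highest-density region of a standard normal has area 2*pi*ln 2", {
  set.seed(131)
  x <- rnorm(2000)
  y <- rnorm(2000)
  bw <- lscvBandwidth(x, y)
  kde <- kdeContours(x, y, bw$h, levels = c(0.50, 0.95))
  a50 <- kde$levels[["0.50"]]$area_km2
  expect_equal(a50, 2 * pi * log(2), tolerance = 0.15)

  # mass self-consistency of the 95% region
  m95 <- kde$levels[["0.95"]]$mass
  expect_gte(m95, 0.94)
  expect_lte(m95, 0.96)

  # nesting: 50% rings lie inside the 95% region
  r50 <- kde$levels[["0.50"]]$rings[[1]]
  expect_true(all(pointInPolygon(r50[, 1], r50[, 2], kde$levels[["0.95"]]$rings)))
})

test_that("density grid integrates to one and matches MASS::kde2d", {
  set.seed(141)
  x <- rnorm(100)
  y <- rnorm(100)
  g <- kdeDensityGrid(x, y, h = c(0.4, 0.4))
  expect_equal(sum(g$z) * prod(g$cell), 1, tolerance = 1e-3)

  skip_if_not_installed("MASS")
  # kde2d divides its h by 4 before using it as a Gaussian sd
  ref <- MASS::kde2d(x, y, h = 4 * 0.4, n = 50, lims = c(range(g$gx), range(g$gy)))
  mine <- kdeDensityGrid(x, y, h = c(0.4, 0.4))
  atx <- ref$x[25]
  aty <- ref$y[25]
  ix <- which.min(abs(mine$gx - atx))
  iy <- which.min(abs(mine$gy - aty))
  expect_equal(mine$z[ix, iy], ref$z[25, 25], tolerance = 0.02)
})

test_that("well-separated clusters produce a two-centre core contour", {
  set.seed(151)
  x <- c(rnorm(150), rnorm(150) + 12)
  y <- c(rnorm(150), rnorm(150))
  kde <- kdeContours(x, y, h = c(0.8, 0.8), levels = 0.50)
  expect_gte(length(kde$levels[["0.50"]]$rings), 2)
  expect_error(kdeContours(x, y, h = c(0.8, 0.8), levels = 1.2), "levels")
})

test_that("centroid of core picks the largest activity centre, west on ties", {
  set.seed(161)
  x <- c(rnorm(250, sd = 1.5), rnorm(50, mean = 14, sd = 0.5))
  y <- c(rnorm(250, sd = 1.5), rnorm(50, sd = 0.5))
  kde <- kdeContours(x, y, h = c(0.9, 0.9), levels = c(0.50, 0.95))
  core <- centroidOfCore(kde)
  expect_lt(abs(core[1]), 1) # centroid of the big cluster at the origin
  expect_lt(abs(core[2]), 1)

  # synthetic tie: two identical rings, westernmost wins
  fake <- structure(list(levels = list("0.50" = list(
    level = 0.5,
    rings = list(
      cbind(c(10, 11, 11, 10), c(0, 0, 1, 1)),
      cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
    ),
    ring_areas = c(1, 1)
  ))), class = "kderesult")
  expect_equal(centroidOfCore(fake), c(0.5, 0.5))
})

test_that("clipping to water halves a polygon straddling a straight coast", {
  g <- rampGrid(lonRange = c(-1, 0.5), latRange = c(-0.5, 0.5), cellsize = 1 / 60)
  frame <- equalAreaFrame(0, 0)
  # square of ~44 x 44 km centred on the coastline (lon 0)
  half <- 22
  ring <- cbind(c(-half, half, half, -half), c(-half, -half, half, half))
  clip <- clipToWater(list(ring), g, frame)
  expect_equal(clip$total_km2, (2 * half)^2, tolerance = 0.05)
  expect_equal(clip$area_km2 / clip$total_km2, 0.5, tolerance = 0.05)

  # fully over water: area unchanged; clipped never exceeds unclipped
  ringW <- ring
  ringW[, 1] <- ringW[, 1] - 60
  clipW <- clipToWater(list(ringW), g, frame)
  expect_equal(clipW$area_km2, clipW$total_km2)
  expect_lte(clip$area_km2, clip$total_km2)
})

test_that("MCP matches exact geometry and hull properties", {
  # 4 corners of a 1-km square
  res <- mcp(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(res$area_km2, 1)
  expect_equal(res$centroid, c(0.5, 0.5))
  expect_false(res$degenerate)

  # adding an interior point changes nothing
  res2 <- mcp(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  expect_equal(res2$area_km2, res$area_km2)
  expect_equal(sort(res2$hull[, 1]), sort(res$hull[, 1]))

  # all points inside or on the hull
  set.seed(171)
  x <- rnorm(40)
  y <- rnorm(40)
  h <- mcp(x, y)
  grown <- h$hull + 1e-9 * (h$hull - matrix(h$centroid, nrow(h$hull), 2, byrow = TRUE))
  expect_true(all(pointInPolygon(x, y, grown)))

  # degenerate: collinear points
  d <- mcp(c(0, 1, 2), c(0, 1, 2))
  expect_true(d$degenerate)
  expect_equal(d$area_km2, 0)
  expect_equal(d$centroid, c(1, 1))
})
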