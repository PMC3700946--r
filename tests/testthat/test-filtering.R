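test_that("LC Z rejection preserves order and conserves the rest", {
  tr <- makeTrack(
    lat = c(29, 29.1, 29.2, 29.3), lon = rep(-88, 4),
    lc = c("3", "B", "Z", "A")
  )
  out <- dropLcZ(tr)
  expect_equal(nrow(out$track), 3)
  expect_equal(out$track$lc, c("3", "B", "A"))
  expect_equal(out$report$dropped$lc_z, 1)
  expect_equal(out$report$retained + sum(unlist(out$report$dropped)), out$report$input)

  allZ <- makeTrack(lat = c(29, 29.1), lon = c(-88, -88.1), lc = "Z")
  outZ <- dropLcZ(allZ)
  expect_equal(nrow(outZ$track), 0)
  expect_equal(outZ$report$dropped$lc_z, 2)
})

test_that("speed filter drops teleporting fixes and is idempotent", {
  # stationary track: nothing dropped
  tr <- makeTrack(lat = rep(29, 10), lon = rep(-88, 10))
  expect_equal(nrow(speedFilter(tr)$track), 10)

  # one teleported outlier: ~500 km east, 8 h gap (62 km/h), then back
  lat <- rep(29, 10)
  lon <- rep(-88, 10)
  lon[5] <- -88 + 500 / (111.195 * cos(29 * pi / 180))
  tr <- makeTrack(lat = lat, lon = lon)
  out <- speedFilter(tr, vmax = 5)
  expect_equal(nrow(out$track), 9)
  expect_equal(out$report$dropped$speed, 1)
  expect_equal(out$track$lon, rep(-88, 9))

  # idempotence: a second pass changes nothing
  again <- speedFilter(out$track, vmax = 5)
  expect_equal(again$track, out$track)

  # consecutive retained speeds all under the limit
  set.seed(91)
  wander <- makeTrack(
    lat = 29 + cumsum(rnorm(50, 0, 0.05)),
    lon = -88 + cumsum(rnorm(50, 0, 0.05))
  )
  filt <- speedFilter(wander, vmax = 5)$track
  n <- nrow(filt)
  sp <- haversineKm(filt$lat[-n], filt$lon[-n], filt$lat[-1], filt$lon[-1]) /
    as.numeric(diff(filt$timestamp), units = "hours")
  expect_true(all(sp <= 5 + 1e-9))
})

test_that("zero time gap between distinct positions drops the later fix", {
  tr <- argosTrack(
    turtle_id = rep("t1", 3),
    timestamp = as.POSIXct("2012-06-01 00:00:00", tz = "UTC") + c(0, 3600, 3600),
    lc = c("1", "1", "1"),
    lat = c(29, 29.01, 29.5), lon = rep(-88, 3)
  )
  out <- speedFilter(tr)
  expect_equal(nrow(out$track), 2)
  expect_equal(out$report$dropped$zero_gap, 1)
})

test_that("land/depth mask keeps the closed [-200, 0) band", {
  g <- rampGrid() # depth = 1000 * lon west of 0; land east
  # depths: -31 (keep), -250 (deep), +2 (land)
  tr <- makeTrack(lat = rep(0, 3), lon = c(-0.031, -0.25, 0.05))
  out <- maskLandAndDeep(tr, g, cutoff = -200)
  expect_equal(nrow(out$track), 1)
  expect_equal(out$track$lon, -0.031)
  expect_equal(out$report$dropped$deep, 1)
  expect_equal(out$report$dropped$land, 1)

  # boundary: exactly -200 retained (closed lower bound)
  trB <- makeTrack(lat = 0, lon = -0.2 + 1 / 120) # cell centre depth == -200 + half-cell
  depth <- depthAt(g, 0, -0.2 + 1 / 120)
  out2 <- maskLandAndDeep(trB, g, cutoff = depth)
  expect_equal(nrow(out2$track), 1)

  # ramp oracle: retained set equals the analytic longitude band
  set.seed(101)
  lon <- runif(200, -0.45, 0.05)
  trR <- makeTrack(lat = runif(200, -0.1, 0.1), lon = lon, stepHours = 1)
  got <- maskLandAndDeep(trR, g, cutoff = -200)$track
  d <- depthAt(g, trR$lat, trR$lon)
  expect_equal(nrow(got), sum(d >= -200 & d < 0))

  # fixes outside the grid: drop-with-log or error
  trOut <- makeTrack(lat = c(0, 5), lon = c(-0.1, -0.1))
  expect_equal(maskLandAndDeep(trOut, g)$report$dropped$off_grid, 1)
  expect_error(maskLandAndDeep(trOut, g, outside = "error"), "outside")
})

test_that("the full filter chain is idempotent", {
  sim <- simConfig(seed = 3, durationDays = 30)
  st <- simulateTrack(sim)
  g <- simulateBathymetry(sim, cellsize = 1 / 30)
  once <- filterTrack(st$fixes, g)
  twice <- filterTrack(once$track, g)
  expect_equal(twice$track, once$track)
  expect_equal(sum(unlist(twice$reports$lc$dropped)), 0)
})

test_that("mean daily locations average per UTC date", {
  base <- as.POSIXct("2012-06-01 00:00:00", tz = "UTC")
  tr <- argosTrack(
    turtle_id = rep("t1", 4),
    timestamp = base + c(0, 6, 12, 30) * 3600,
    lc = "1",
    lat = c(29.0, 29.2, 29.4, 30.0), lon = c(-88, -88, -88, -88.5)
  )
  mdl <- meanDailyLocations(tr)
  expect_equal(nrow(mdl), 2)
  expect_equal(mdl$lat[1], 29.2) # mean of 29.0, 29.2, 29.4
  expect_equal(mdl$n_fixes, c(3L, 1L))

  # one fix per date: identity
  tr1 <- makeTrack(lat = 29 + (0:5) / 10, lon = rep(-88, 6), stepHours = 24)
  mdl1 <- meanDailyLocations(tr1)
  expect_equal(mdl1$lat, tr1$lat)

  # 61-day track with >= 1 fix per day meets the 20-location kernel rule
  tr61 <- makeTrack(lat = rep(29, 61 * 3), lon = rep(-88, 61 * 3), stepHours = 8)
  expect_gte(nrow(meanDailyLocations(tr61)), 20)
})
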