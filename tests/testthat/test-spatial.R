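test_that("grid construction keeps only shelf-water cells of ~100 km^2", {
  g <- shelfGrid()
  og <- buildGrid(c(-0.25, 0.25), c(-0.65, -0.15), g, cellKm = 10)
  # 50 x 50 km all-water extent: about 25 cells (grid origin alignment can
  # add a boundary row/column; all cells must be shelf water)
  expect_gte(nrow(og$cells), 25)
  expect_true(all(og$cells$depth_m < 0 & og$cells$depth_m > -200))

  # extent fully on land errors
  expect_error(buildGrid(c(-0.1, 0.1), c(0.05, 0.25), g, cellKm = 10), "no shelf-water")
})

test_that("turtle-days counts distinct turtle-date-cell triples", {
  g <- shelfGrid()
  og <- buildGrid(c(-0.4, 0.4), c(-0.9, -0.1), g, cellKm = 10)
  base <- as.POSIXct("2012-06-01 00:00:00", tz = "UTC")

  # 1 turtle, 3 fixes in one cell on one date -> 1 turtle-day
  cell1 <- og$cells[1, ]
  tr <- argosTrack(
    turtle_id = rep("a", 3), timestamp = base + (0:2) * 3600, lc = "1",
    lat = rep(cell1$lat, 3), lon = rep(cell1$lon, 3)
  )
  td <- turtleDays(tr, og)
  expect_equal(td$cells$turtle_days[1], 1L)
  expect_equal(sum(td$cells$turtle_days), 1L)

  # 2 turtles, same cell, same date -> 2
  tr2 <- argosTrack(
    turtle_id = c("a", "b"), timestamp = rep(base, 2), lc = "1",
    lat = rep(cell1$lat, 2), lon = rep(cell1$lon, 2)
  )
  expect_equal(turtleDays(tr2, og)$cells$turtle_days[1], 2L)

  # brute-force conservation on a random fixture
  set.seed(211)
  n <- 300
  trR <- argosTrack(
    turtle_id = sample(c("a", "b", "c"), n, TRUE),
    timestamp = base + sort(sample.int(20 * 86400, n)),
    lc = "1",
    lat = runif(n, -0.3, 0.3), lon = runif(n, -0.9, -0.2)
  )
  tdR <- turtleDays(trR, og)
  idx <- internest:::cellIndexOf(og, trR$lat, trR$lon)
  manual <- unique(data.frame(
    t = trR$turtle_id, d = as.Date(trR$timestamp, tz = "UTC"), c = idx
  ))
  manual <- manual[!is.na(manual$c), ]
  expect_equal(sum(tdR$cells$turtle_days), nrow(manual))
  expect_equal(nrow(tdR$visits), nrow(manual))
})

test_that("Poisson GLM recovers a known depth effect and the closed-form intercept", {
  set.seed(221)
  n <- 500
  depth <- rnorm(n)
  lam <- exp(1 + 0.5 * depth)
  cells <- data.frame(turtle_days = rpois(n, lam), depth_m = depth)
  fit <- glmTurtleDays(cells, "depth_m")
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "depth_m"], 0.5, tolerance = 0.1)
  expect_true(est$significant[est$term == "depth_m"])

  # intercept-only model equals log of the mean exactly
  fit0 <- glmTurtleDays(cells, character(0))
  expect_equal(
    fit0$coefficients$estimate[1],
    log(mean(cells$turtle_days)),
    tolerance = 1e-8
  )
})

test_that("pure-noise covariates are significant at most rarely", {
  set.seed(231)
  hits <- 0L
  for (r in 1:20) {
    n <- 200
    cells <- data.frame(turtle_days = rpois(n, 3), noise = rnorm(n))
    fit <- glmTurtleDays(cells, "noise")
    z <- with(fit$coefficients, abs(estimate[term == "noise"] / se[term == "noise"]))
    if (z >= 2) hits <- hits + 1L
  }
  expect_lte(hits / 20, 0.10)
})

test_that("platform buffer counting is boundary-inclusive and removal-aware", {
  kmPerDeg <- 2 * pi * 6371.0088 / 360
  mk <- function(dKm, active = TRUE) {
    data.frame(
      platform_id = "p", lat = dKm / kmPerDeg, lon = 0,
      removal_date = if (active) "" else "2010-01-01",
      active = active
    )
  }
  expect_equal(platformsWithinBuffer(0, 0, mk(9.99)), 1L)
  expect_equal(platformsWithinBuffer(0, 0, mk(10.01)), 0L)
  expect_equal(platformsWithinBuffer(0, 0, mk(1, active = FALSE)), 0L)

  # exhaustive-scan oracle on 1000 random platforms
  set.seed(241)
  pf <- data.frame(
    platform_id = sprintf("p%d", 1:1000),
    lat = runif(1000, -0.5, 0.5), lon = runif(1000, -0.5, 0.5),
    removal_date = "", active = runif(1000) > 0.3
  )
  got <- platformsWithinBuffer(c(0, 0.2), c(0, -0.1), pf, rKm = 25)
  for (i in 1:2) {
    cLat <- c(0, 0.2)[i]
    cLon <- c(0, -0.1)[i]
    manual <- sum(vapply(seq_len(1000), function(k) {
      pf$active[k] && haversineKm(cLat, cLon, pf$lat[k], pf$lon[k]) <= 25
    }, logical(1)))
    expect_equal(got[i], manual)
  }
})

test_that("trawl bands honour the printed closed-interval boundaries", {
  zones <- data.frame(
    zone_id = c("z1", "z2", "z3", "z4"),
    lat_min = c(0, 1, 2, 3), lat_max = c(1, 2, 3, 4),
    lon_min = -2, lon_max = 0,
    effort_days = c(2000, 4, 1500, 1501)
  )
  got <- trawlCategory(c(0.5, 1.5, 2.5, 3.5), rep(-1, 4), zones)
  expect_equal(got$trawl_days, c(2000, 4, 1500, 1501))
  expect_equal(got$band, c("1501-3000", "4", "5-1500", "1501-3000"))

  # centroid in no zone: explicit missing
  out <- trawlCategory(10, -1, zones)
  expect_true(is.na(out$trawl_days))
  expect_true(is.na(out$band))
})
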