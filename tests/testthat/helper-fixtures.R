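# Shared in-code fixtures for the test suite.

# small synthetic shelf: land at lon >= 0, water deepening westward
# (10 m per 0.01 degree), 1/60-degree cells
rampGrid <- function(lonRange = c(-0.5, 0.1), latRange = c(-0.2, 0.2),
                     cellsize = 1 / 60) {
  lon <- seq(lonRange[1] + cellsize / 2, lonRange[2] - cellsize / 2, by = cellsize)
  lat <- seq(latRange[1] + cellsize / 2, latRange[2] - cellsize / 2, by = cellsize)
  vals <- outer(lat, lon, function(la, lo) ifelse(lo >= 0, 2, 1000 * lo))
  bathymetryGrid(lonRange[1], latRange[1], cellsize, vals)
}

# gentler shelf for fidelity/grid tests: -200 m reached one degree offshore,
# so the 0 to -200 m water domain spans lon (-1, 0)
shelfGrid <- function(lonRange = c(-1.4, 0.2), latRange = c(-1, 1),
                      cellsize = 1 / 30) {
  lon <- seq(lonRange[1] + cellsize / 2, lonRange[2] - cellsize / 2, by = cellsize)
  lat <- seq(latRange[1] + cellsize / 2, latRange[2] - cellsize / 2, by = cellsize)
  vals <- outer(lat, lon, function(la, lo) ifelse(lo >= 0, 2, 200 * lo))
  bathymetryGrid(lonRange[1], latRange[1], cellsize, vals)
}

# minimal in-memory track builder
makeTrack <- function(lat, lon, lc = "1", id = "t1",
                      start = as.POSIXct("2012-06-01 00:00:00", tz = "UTC"),
                      stepHours = 8) {
  n <- length(lat)
  argosTrack(
    turtle_id = rep(id, n),
    timestamp = start + (seq_len(n) - 1) * stepHours * 3600,
    lc = rep(lc, length.out = n),
    lat = lat, lon = lon
  )
}

expectedCounts <- list(table1 = 40L, table2 = 10L, table3 = 11L)
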