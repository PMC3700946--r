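# internest

Movement analysis of satellite-tagged nesting sea turtles during the
inter-nesting period — the weeks a female spends at sea between successive
nesting emergences. Nesting loggerheads in places like the northern Gulf of
Mexico carry Argos transmitters whose positions are irregular in time and
contaminated by heavy-tailed, quality-classed errors; the scientific
questions are where the turtles actually go between nests, how faithful they
are to nesting beaches and to in-water sites, and how much their habitat
overlaps shrimp-trawling grounds and oil and gas platforms. `internest`
packages that full analysis chain for movement ecologists:

* **Filtering** — Argos location-class rejection (LC Z), a 5 km/h
  forward-sweep swim-speed filter, land and neritic-depth (−200 m) masking
  against an ESRI ASCII bathymetry grid, and reduction to mean daily
  locations.
* **Behavioural segmentation** — a two-state switching correlated random
  walk state-space model on regular 8-h steps. Position differences follow
  `d_t ~ N2(γ_b T(θ_b) d_{t−1}, Σ)` with a hidden 2-state Markov chain `b`
  (migration vs inter-nesting) and per-location-class Student-t observation
  errors; the posterior is sampled by a compiled Metropolis-within-Gibbs /
  forward-filtering backward-sampling engine with two chains and
  Gelman–Rubin monitoring.
* **Home ranges** — fixed-kernel utilisation distributions with
  least-squares cross-validation bandwidths, 50 %/95 % probability contours
  clipped to water, minimum convex polygons, and activity-centre centroids.
* **Site fidelity** — a Monte Carlo random-walk test (100 replicates,
  step-length-preserving nulls bounded to the 0 to −200 m domain) and the
  classical 5-km nest-site-fidelity rule, plus emergence interval/distance
  statistics.
* **Occupancy and threats** — 10 × 10 km turtle-day grids, a Poisson
  log-link model of grid-cell use, platform-buffer counts and trawl-effort
  bands.
* **A generative simulator** of switching-CRW tracks observed through
  Argos-like errors over a synthetic shelf, used for end-to-end validation,
  plus packaged numeric fixtures of the study's three printed summary
  tables.

## Worked example

Simulate a 120-day track from the generative model, fit the switching CRW,
and extract the inter-nesting period:

```r
library(internest)

sim <- simConfig(constrainToWater = FALSE)   # exact generative twin
st  <- simulateTrack(sim)
tr  <- dropLcZ(st$fixes)$track

cfg <- runConfig(mcmcIterations = 3000, mcmcBurnin = 2000, mcmcThin = 5)
fit <- fitDCRWS(tr, cfg, seed = 1)
fit
#> switching CRW fit: turtle sim01, 360 states at 8 intervals
#>   gamma = (0.86, 0.11), alpha = (0.93, 0.10), max Rhat = 1.005
#>   steps:  internesting=106, migration=169, uncertain=84

extractInternestingPeriod(fit, captureDate = as.Date("2012-06-01"))
#> $turtle_id
#> [1] "sim01"
#> $start
#> [1] "2012-06-01"
#> $end
#> [1] "2012-09-26"
#> $days
#> [1] 118
```

The simulation truth used γ = (0.8, 0.2) and α = (0.95, 0.10): the posterior
means land within ±0.15 of both persistence parameters and the step-state
classification agrees with the simulated states at ~90 %. `gamma = (0.86,
0.11)` says state 1 is strongly persistent (directed migration) and state 2
weakly persistent (area-restricted inter-nesting); `max Rhat = 1.005` says
the two chains mixed. The inter-nesting period spans tagging to the last
step classified inter-nesting (118 of the 120 simulated days here).

Home-range estimation from the track's mean daily locations:

```r
mdl   <- meanDailyLocations(tr)
frame <- frameForPoints(mdl$lat, mdl$lon)
xy    <- frame$forward(mdl$lat, mdl$lon)
bw    <- lscvBandwidth(xy$x, xy$y)
kde   <- kdeContours(xy$x, xy$y, bw$h)
kde
#> kernel home range, h = 7.446 3.699 km
#>   50%: 9 ring(s), 3824.0 km^2 (grid mass 0.500)
#>   95%: 12 ring(s), 16928.6 km^2 (grid mass 0.950)
```

The 50 % contour is the core-use area, the 95 % contour the overall range
(this whole-track example mixes migration and inter-nesting locations, hence
the many activity centres; the pipeline computes kernels per inter-nesting
period). Areas are km² in a local equal-area frame — the per-axis bandwidths
differ because the latitude/longitude spreads were unequal and the data were
rescaled to select a single bandwidth — and `clipToWater()` removes any
land inside a contour before an area is reported. The printed-table fixtures
and their summary statistics (e.g. the 61.9 km² mean core area, the pooled
27.5 km mean distance between successive emergences) are available through
`loadFixture()` and `summarizeTables()`.

A stage-by-stage command-line pipeline is available through
`internestCli()` (see `inst/scripts/internest-cli.R`):
`simulate`, `filter`, `ssm`, `homerange`, `fidelity`, `grid`, `threats`,
`summarize`, or `all` over a working directory.

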