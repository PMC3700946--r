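---
title: "Methods: inter-nesting movement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-nesting movement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`internest` re-implements, as a tested pipeline, the analysis chain used to
study the inter-nesting movements of satellite-tagged nesting loggerhead
turtles: Argos track filtering, switching state-space segmentation of
behaviour, kernel and convex-polygon home ranges, a Monte Carlo site-fidelity
test, occupancy-grid modelling, and overlap scoring against trawling and
platform threat layers. This vignette records the models, the tunable
parameters, the numerical choices, and the places where the design was
genuinely open.

## Track filtering

Argos positions carry a quality class (3, 2, 1, 0, A, B, Z). Class Z fixes
have no error estimate and are discarded outright. The remaining fixes pass a
forward-sweep swim-speed filter: the first fix is kept, and each later fix is
dropped when the great-circle speed from the last *retained* fix exceeds the
limit (default 5 km/h, a biological cap on sustained loggerhead swimming).
The forward sweep is the simplest deterministic rule consistent with a bare
speed limit; it guarantees all retained consecutive speeds are legal and that
a second pass changes nothing. Fixes on land or seaward of the neritic cutoff
(default −200 m, the shelf edge; the lower bound is closed, so a fix at
exactly −200 m survives) are then masked against a bathymetry grid by
nearest-cell lookup. For kernel analyses the filtered fixes are reduced to
*mean daily locations* — the arithmetic per-UTC-date mean of latitude and
longitude — to damp serial autocorrelation; arithmetic longitude averaging is
guarded by an assertion that the track spans no antimeridian.

All distances are haversine on a sphere of radius 6371.0088 km. The printed
quantities this pipeline reproduces carry 0.1-km precision, two orders above
the < 0.5 % sphere-vs-ellipsoid error. Areas are computed by the shoelace
formula in a local Lambert azimuthal equal-area frame centred on each point
set, which is exact in km² to first order near the reference point.

## Switching state-space model

Movement is modelled as a two-state switching first-difference correlated
random walk on a regular 8-hour grid anchored at the first fix's timestamp
truncated to the hour. With `d_t = x_t − x_{t−1}`,

`d_t ~ N2( gamma[b_t] * T(theta[b_t]) * d_{t−1}, diag(sigma_lon², sigma_lat²) )`

where `T` is a rotation, `gamma` in [0, 1] is move persistence, and `b_t` is
a hidden two-state Markov chain with transition probabilities `alpha1 =
P(1→1)` and `alpha2 = P(2→1)`. State 1 is migration (directed, persistent)
and state 2 inter-nesting/foraging; identifiability is enforced by the
ordering `gamma1 > gamma2`. Each irregular fix relates to its bracketing
states by linear interpolation at fractional position `j`, plus independent
per-coordinate Student-t errors whose degrees of freedom and scale are fixed
per location class and inflated by one free scale `psi`. The class constants
(df 10/8/6/4/4/3 and scales 0.25/0.4/0.8/1.7/1.0/1.9 km for 3/2/1/0/A/B) are
calibration-style values consistent with the published accuracy bands for
Kalman-processed Argos data, where classes A and B are substantially better
than class 0; they ship in `runConfig()` so they are auditable, and the
simulator uses the same constants.

The posterior is sampled by a compiled Metropolis-within-Gibbs scheme:

* single-site random-walk Metropolis on each latent position, five sweeps per
  iteration, with a 10 % wide-proposal mixture and a 20 % *anchored
  independence proposal* that jumps a position back to the data
  interpolation — heavy-tailed observation errors otherwise let the path
  drift away from fixes too cheaply;
* collapsed random-walk Metropolis for `gamma`, `theta` and `sigma` with the
  hidden chain marginalised by the forward algorithm, after which the chain
  is redrawn by forward-filtering backward-sampling and `alpha` by its
  conjugate Beta conditional (a partially collapsed Gibbs step). Collapsing
  is essential: conditioning on a fixed state allocation creates a
  self-reinforcing single-regime mode that plain Gibbs cannot leave;
* a log random walk for `psi`, held at 0.3 for the first half of burn-in so
  the warm-up path tracks the data closely before the error scale is freed;
* step sizes adapted only during burn-in (acceptance targets 0.3 for
  positions, 0.35 for parameters), frozen afterwards, so the post-burn-in
  kernel is fixed.

Two chains are run (defaults: 10 000 kept iterations after 7 000 burn-in,
thinned by 5; the validation suite uses a reduced 3 000/2 000 budget), with
mildly jittered parameter starts; the latent path always starts at the data
interpolation, because jittering it erases the two-regime step structure the
sampler must find. Convergence is monitored by the two-chain Gelman–Rubin
statistic per parameter. When any statistic exceeds 1.1 the fit is
re-attempted from a derived seed (at most twice), mirroring the standard
practice of re-running non-converged MCMC; a fit that still fails is returned
flagged `notPossible` and routed to the non-SSM summary path, which is how
tracks for which the state-space model "was not possible" are handled
downstream.

The posterior mean state index `b̄ ∈ [1, 2]` is classified per step as
migration below 1.25, inter-nesting above 1.75, uncertain between — the
cutoff convention of the model's originating literature; the inter-nesting
period runs from the tagging date to the date of the last inter-nesting step,
inclusive of interleaved migration steps.

## Home ranges

Kernel home ranges use a Gaussian product kernel in the equal-area frame.
The bandwidth minimises the least-squares cross-validation score over 50
log-spaced candidates in [0.05 σ, 2 σ]; when the axis standard deviations
differ by more than 10 % the coordinates are rescaled to unit variance, one
bandwidth is chosen, and it is back-scaled per axis. The density is evaluated
on a grid padded three bandwidths beyond the point extent at a resolution of
at most h/3; probability contours (defaults 0.50 and 0.95) are the
highest-density regions whose enclosed grid mass matches the level, extracted
by marching squares at the mass-matched threshold. Land inside a contour is
removed by rasterising the rings at 0.5 km and discarding cells whose centre
bathymetry is at or above sea level, matching the convention that reported
areas are in-water only. Tracks with fewer than 20 mean daily locations fall
back to the 100 % minimum convex polygon. When a 50 % contour splits into
several activity centres the centroid of the largest is reported, with an
exact-area tie broken by the westernmost centroid.

## Site fidelity

In-water site fidelity is tested against 100 random walks that keep the
observed step-length sequence, draw headings uniformly, start at the observed
start, and stay inside the 0 to −200 m water domain (a step leaving the
domain is re-drawn up to 100 times, then reflected about the previous point).
The statistic is the mean squared displacement from the first point; the
track shows site fidelity when it is less dispersed than at least 95 of the
100 walks. The statistic is computed in the equal-area kilometre frame
*without* per-axis unit-variance standardisation: the frame already removes
the latitude/longitude scale anisotropy that historically motivated
standardising, and standardising each axis on top of it would make a
perfectly directed track look compact in its own units — exactly the
behaviour the test must detect. Nest-site fidelity on the beach is the
classical rule: successive emergences at most 5 km apart (boundary
inclusive).

## Occupancy grid and threats

Occupancy uses axis-aligned 10 × 10 km cells in the equal-area frame, clipped
to shelf water (centre depth strictly between −200 and 0 m). A turtle-day is
one UTC calendar day with at least one fix by one turtle in one cell; a
turtle visiting two cells on one day credits each. Turtle-days are modelled
with a Poisson log-link GLM fit by IRLS (relative tolerance 1e-8, at most 100
iterations) with Wald chi-square tests at alpha 0.05; the Poisson family is
the canonical choice for the count response, recorded in the output metadata
because the source analysis named only "GLM with log-transformation".
Threat scoring counts non-removed platforms within an inclusive 10-km
haversine buffer of each centroid and assigns the trawl-effort band of the
zone containing the centroid using the four closed reported intervals
(4, 5–1500, 1501–3000, 3001–7000 days).

## Synthetic data

No raw telemetry was deposited with the study, so validation runs on a
generative twin. The simulator draws the hidden chain and the switching CRW
exactly as the state-space model assumes, schedules fixes as a Poisson stream
(default 6/day — a realistic daily yield for a 24-h duty-cycle tag under
Kalman processing) over a location-class mixture weighted toward A and B
(0.05/0.08/0.12/0.15/0.25/0.35), adds the per-class t errors, and injects a
2 % fraction of LC Z junk and 1 % land-side outliers for filter testing. The
release fix at tagging time is emitted deliberately: it is realistic (the
release position is known), and it pins the 8-h regularisation grid to the
generative grid so parameter recovery measures the sampler rather than a
grid-phase artefact. The world is a straight meridional coast with a linear
shelf reaching −200 m at 150 km offshore, two beaches ~250 km apart for the
long-range nest-swap scenario, and a ~14-day re-nesting interval.

Two features of real data are deliberately absent: coastline complexity and
any oceanographic forcing. One consequence matters for validation design:
when the simulated path is constrained to water (the default), tracks that
brush the coast have their inter-nesting dynamics censored by the boundary,
which is outside the fitted model; parameter-recovery checks therefore
simulate the unconstrained process (`constrainToWater = FALSE`), while
pipeline-level checks (filtering, home ranges, fidelity) keep the constraint.
Passing tests show the estimator is correct for data from its own model
family; they cannot show that real Gulf tracks follow that family.

## Problem sizes and tolerances

The validation suite uses a 120-day track (361 8-h states, ~700 fixes) with
truth gamma = (0.8, 0.2), theta = (0, pi), alpha = (0.95, 0.10), sigma =
0.03°, and a reduced MCMC budget of 2 × 3000 kept iterations after 2000
burn-in, thinned by 5 — enough for posterior means of gamma within ±0.15 and
step-state accuracy above 0.80. Kernel contours are checked against the
closed-form 50 % highest-density area of the standard bivariate normal,
2 π ln 2 ≈ 4.355, within 15 % at n = 2000 draws, and 95 % mass
self-consistency within ±0.01. Convex hulls are compared with an all-pairs
orientation brute force. The density grid is required to integrate to 1 ±
1e-3. The fidelity test must pass a constructed resident cluster with all
100 nulls more dispersed, fail a ballistic track, and pass unconstrained null
walks at most 10 % of the time over 50 replicates. The occupancy GLM must
recover a slope of 0.5 within ±0.1 at 500 cells and reproduce the
intercept-only closed form exactly.

## Known limitations

* The sampler reports the dominant posterior mode under the `gamma1 >
  gamma2` ordering; in weakly informative tracks (few regime switches) the
  persistence parameters can remain broad, which the Gelman–Rubin flag
  surfaces but cannot repair.
* Turn-angle parameters are effectively unidentified when the corresponding
  `gamma` is near zero; their posteriors then echo the prior.
* The occupancy model ignores spatial autocorrelation between cells, as did
  the source analysis.
* Bathymetry lookups are nearest-cell; distance-to-shore resolves to the
  nearest land-cell centre, so both carry an error of order one cell width.
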