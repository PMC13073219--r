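---
title: "Methods: simulating dual dispatch of EMS and volunteer fire services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating dual dispatch of EMS and volunteer fire services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Survival after out-of-hospital cardiac arrest falls steeply with every
minute until chest compressions start. The response time — alarm to
curbside arrival — has two parts: *turnout time* (alarm to vehicle
departure) and *travel time* (station to scene along the fastest route).
Volunteer fire services are far more densely distributed than ambulance
stations, but their crews must usually travel to the station first, so
their turnout times are longer. `dualdispatch` asks, by simulation, whether
alerting the fire service *in addition to* EMS still shortens arrival
times, and where.

For each simulated arrest the package computes

* the EMS-only response `ems_turnout + ems_travel`,
* the fire response `fire_turnout + fire_travel`, and
* the dual-dispatch response `min(ems_response, fire_response)`,

and labels the event's *first arriver* (FIRE only when the fire response is
strictly smaller; exact ties count as EMS-first, which makes the reported
fire-first fraction conservative).

## The synthetic study region

Real analyses of this kind need station registries, a population raster and
a road router. To keep every stage runnable and testable offline, the
package generates a synthetic region whose *statistical* structure mirrors
a large, heterogeneous federal state:

* **Area and population.** Defaults: 160 km × 120 km (19,200 km²), 1.73
  million inhabitants on a 2-km raster.
* **Density surface.** A rural background (10 inhabitants/km²) plus 80
  Gaussian settlement clusters with spreads of 1.5–5 km drawn per cluster
  and gamma-distributed masses holding 70% of the population before
  renormalisation; the raster is rescaled so its mass equals the configured
  population exactly. This reproduces the contrast between sparsely
  populated countryside and dense peri-urban clusters; with zero clusters
  the renormalisation makes the raster exactly uniform, which anchors the
  unit tests.
* **Road network.** 2,000 nodes sampled with probability increasing in
  local population (plus a rural floor of 10% of the mean cell mass so the
  countryside keeps roads), a 4-nearest-neighbour scaffold, closest-pair
  bridges between components (guaranteeing one connected component by
  construction), and 5% long-range highway edges of at least 20 km. Speed
  classes: urban 40 km/h (midpoint density ≥ 300/km²), rural 70 km/h,
  highway 100 km/h. These values were chosen so that travel times at
  regional scale span roughly 1–25 minutes, the range a fastest-route
  router produces over such a region; with them the default network has a
  mean degree near 5 and EMS travel times with a median near 5 min and a
  99th percentile near 23 min.
* **Stations.** 121 EMS stations placed by population-weighted sampling of
  raster cells without replacement (demand-driven placement) and 1,590 fire
  stations by an equal blend of population weighting and uniform sampling
  over settled cells (municipal ubiquity) — a 13:1 ratio. Stations snap to
  the nearest network node not already holding a station of the same
  service. When stations are sparse relative to nodes this is exactly the
  nearest node; at the default density (1,590 fire stations on 2,000 nodes)
  the exclusivity rule occasionally forces the next-nearest node, a
  discretisation we accept to keep nearest-station sets well defined.

The generator is deterministic given the seed: the region uses
`config$seed`, the network `seed + 1`, the stations `seed + 2`, and the
pipeline draws events with `seed + 3`.

What the generator does **not** emulate: real road topology (one-way
streets, turn restrictions, congestion), geodesic coordinates (everything
is planar km), day/night turnout differences, unit unavailability and
simultaneous missions, and the actual spatial layout of any real station
registry. Passing tests therefore demonstrate the *mechanism* — dense fire
coverage converts into earlier arrivals despite longer turnout — not the
numeric response times of any real region.

## Events and routing

Arrest locations are sampled in two stages: a raster cell with probability
proportional to its population, then a uniform position within the cell.
The two-stage design makes weight fidelity exactly testable (a chi-square
test of cell counts against cell weights) and guarantees that zero-density
cells never receive events. Events snap to the nearest network node with no
off-road penalty; the clock stops at the curb, so building access and time
to patient contact are outside the model.

Travel times are shortest-path times on the speed-weighted graph (Dijkstra,
via igraph). Following common dispatch practice the pipeline routes only
the `k = 10` Euclidean-nearest stations per service and keeps the fastest —
the straight-line metric is the only one computable before routing. The
exact mode (`k = all`) is kept as an in-package oracle: the test suite
audits the prefilter against the exhaustive minimum and reports the
mismatch rate (well under 5% of events on audited instances), and an
independently implemented Bellman–Ford oracle checks the router itself.
Because edges are undirected, station-to-event and event-to-station times
coincide.

## Turnouts and scenarios

Defaults are 2 min (EMS) and 5 min (fire) — daytime values for a system
where most fire crews are volunteers — with an 8-min fire-turnout
sensitivity scenario, mirroring the dispatch rule that checks after eight
minutes whether the fire service has left. Both values are configurable;
no separate day/night analysis is performed. Travel times do not depend on
turnout, so all scenarios and the sweep reuse one cached travel table.

## Statistics

* **Summaries.** Mean, sample SD (n−1), linearly interpolated percentiles
  (`quantile` type 7), coverage fractions with inclusive thresholds
  (default 10 min), and the strict fire-first fraction.
* **Strategy comparison.** The headline comparison is a paired two-sided
  t-test on per-event differences (both strategies are evaluated on the
  same events). If every difference is zero the degenerate result t = 0,
  p = 1 is returned rather than an error.
* **Turnout sweep.** The sweep re-runs dispatch and test over a fire-turnout
  grid (default 2–25 min in 1-min steps, α = 0.05, no multiple-testing
  correction — the analysis is exploratory) and reports the smallest
  turnout at which significance is lost. Here the *Welch two-sample* test
  is the default, deliberately: paired differences are non-negative by
  construction (dual dispatch can never be slower than EMS alone), so a
  paired test stays significant as long as *any* handful of events still
  benefits, and a "turnout beyond which the groups no longer differ" would
  essentially never exist. The sweep's question — when do the two
  arrival-time *distributions* stop being distinguishable — is a
  between-group question, and the Welch test answers it; `test = "paired"`
  remains available.
* **Regression.** A Gaussian-family, identity-link GLM of response time on
  population density (untransformed, inhabitants/km²), a dual-dispatch
  indicator, and their interaction, fitted on the long format (two rows per
  event). R² is 1 − RSS/TSS. A rank-deficient design (e.g. constant
  density) errors naming the collinear column. The expected pattern — and
  what the acceptance checks assert — is a negative density coefficient
  (denser areas are reached faster) with a positive interaction (the dual
  advantage shrinks as density grows).

## Numerical choices and degenerate inputs

* Ties: equal response times count as EMS-first; equal routed times break
  by station id (ascending); equal Euclidean prefilter distances likewise.
* Raster mass is renormalised to the configured population after cluster
  placement (conservation holds to float precision, tested at 0.1%).
* `fire_turnout = Inf`-like values (e.g. `1e6`) recover EMS-only exactly
  and drive the paired test to p = 1 via the all-zero-differences rule.
* An all-zero raster, an empty record set, unsorted sweep grids, unknown
  node ids and unreachable destinations raise immediate errors rather than
  propagating infinities.

## Problem sizes

The default study instance is 1,000 events on the full-scale region (2,000
nodes, 1,711 stations) and runs in a few seconds on one core. The test
suite uses this instance for the end-to-end checks and smaller instances
(250–800 nodes) for exhaustive oracles: 20 fifty-node networks × 100 pairs
against Bellman–Ford, a 400-event exact-versus-prefilter audit, and 200
replicates of n = 2,000 for regression coverage. These sizes were chosen so
each property is checked exhaustively where exhaustiveness is the point and
at study scale where scale is the point.

## Limitations

Beyond the generator gaps listed above, the model assigns every event the
density of its raster cell (the regression covariate inherits the raster
resolution), assumes both services drive the same fastest routes with no
service-specific speed adjustments, and treats stations as always staffed
and available. Absolute response times from any synthetic instance should
be read as illustrative; the supported conclusions are the comparative and
structural ones the tests assert.
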