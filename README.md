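# dualdispatch

Simulation of out-of-hospital cardiac-arrest (OHCA) response times under
two dispatch strategies: sending the emergency medical service (EMS) alone,
or *dual dispatch* — simultaneously alerting EMS and the volunteer fire
service and counting the earlier arrival. It is aimed at EMS researchers
and dispatch planners who want to quantify, before a field trial, how much
a region's dense fire-station coverage can offset the longer turnout times
of volunteer crews.

For each simulated arrest *i* and service *s* the model computes

    response_i(s) = turnout(s) + travel_i(s)

where `travel_i(s)` is the fastest-route time on a speed-weighted road
network from the event to the best of the `k = 10` straight-line-nearest
stations of service *s*, and

    dual_i = min( response_i(EMS), response_i(FIRE) ).

Strategies are compared by mean response, 90th percentiles, coverage within
10 minutes, the fraction of events the fire service reaches first, a
fire-turnout sensitivity sweep (at which turnout does the advantage
vanish?), and a Gaussian GLM

    response ~ β0 + β_d · density + β_s · dual + β_i · density × dual

whose negative `β_d` and positive `β_i` express that dense areas are
reached faster and that the dual-dispatch advantage is largest where
population is sparse.

Everything runs offline: a generator builds a synthetic study region
(population-density raster, connected road network with urban / rural /
highway speed classes, and population-weighted station sets) whose
statistical structure mirrors a large heterogeneous federal state —
~19,000 km², 1.73 M inhabitants, 121 EMS vs 1,590 fire stations (13:1).
Adapters read external station GeoJSON and ASCII-grid rasters into the same
pipeline. See `vignette("dual-dispatch-methods")` for the model and every
tunable parameter.

## Worked example

```r
library(dualdispatch)

cfg <- geography_config()            # Lower-Austria-like defaults, seed 42
run <- run_dual_dispatch(cfg, n_events = 1000)
print(run)
```

```
<dual_dispatch_run> 1000 events, 121 EMS / 1590 fire stations
  base: EMS-only 7.8 min (SD 4.7) vs dual 4.8 min (SD 1.3); fire first 61.8%
  turnout8: EMS-only 7.8 min (SD 4.7) vs dual 6.3 min (SD 2.3); fire first 36.5%
<sweep_result> 24 turnout values, alpha=0.05, threshold=15 min
<density_glm> n=2000 R^2=0.240
  beta: intercept=9.242 density=-0.00445 strategy=-4.264 interaction=0.003885
```

Reading this: with 2-min EMS and 5-min fire turnouts, adding the fire
service cuts the mean arrival time by 3 minutes and the fire crew is first
at the scene in 62% of events; with the 8-min sensitivity turnout the
advantage shrinks but persists; raising the fire turnout to 15 min makes
the two strategies' arrival-time distributions statistically
indistinguishable on this instance; and the regression signs show the
benefit concentrating in low-density areas.

Persist a run and build the JSON report plus figures (strategy boxplots and
a map of events coloured by first arriver over log-density shading):

```r
run <- run_dual_dispatch(cfg, n_events = 1000, out_dir = "run1")
# run1/report.json, run1/fig_distributions.png, run1/fig_map.png, CSV/GeoJSON state
```

A thin command-line front end lives at `inst/cli/dualdispatch.R`
(`generate`, `simulate`, `report` subcommands).

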