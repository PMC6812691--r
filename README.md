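# raftr

Analysis pipeline for seabird **rafting** — flocks of birds sitting on the
sea surface near their breeding colony. Around many island colonies of
burrow-nesting seabirds (the motivating system is Manx shearwaters around
a small Welsh island), rafting structures the birds' day: rafts sit well
offshore in daylight, leaving a "halo" of empty water along the shore, and
close in toward the colony after dark. `raftr` is aimed at movement
ecologists who hold one or both of the two standard data streams for this
behaviour:

* **shore observations** — clifftop compass + inclinometer sightings of
  rafts with bird counts, and
* **GPS biologging tracks** — 5-minute fixes from birds tagged at the
  colony,

plus supporting weather and tide series.

## What it computes

1. **Raft geolocation.** An observer at cliff height *C* (instrument
   height *H*, tide *T*) reading an inclinometer angle *D* below the
   horizontal is at range *r* = (*C* + *H* − *T*)/tan *D* from the raft;
   positions follow by great-circle projection along the bearing, with
   distance-to-shore against a densified shoreline polygon and a 2,000 m
   retention boundary.
2. **Behavioural classification.** Between-fix speeds (Vincenty geodesic
   over elapsed time, 30 m/s error filter) are modelled as a
   two-component normal mixture fitted by EM; the rafting/flying
   threshold is the equal-posterior speed — the root of
   λ₁φ(s; μ₁, σ₁) = λ₂φ(s; μ₂, σ₂) between the means. Segments are
   annotated day/night (solar elevation < −0.833°) and by study radius.
3. **Wind-direction effects.** Von Mises fits and the
   Jammalamadaka–Sarma circular correlation between rafting direction
   and wind direction, with asymptotic and permutation p-values.
4. **Raft size vs wind speed.** Generalized least squares of log raft
   size on wind speed with moving-average MA(4) error correlation nested
   within Julian day, fitted from first principles (profiled β/σ², REML
   or ML, Monahan-transformed Nelder–Mead over θ).
5. **Diel trends.** Cyclic penalized smooths of bird counts (Poisson) and
   shore distance (Gaussian, per-bird random intercept) over the 24 h
   cycle.
6. **Synthetic data.** Seeded generators for every input, with known
   ground truth, so the whole pipeline is testable end to end with no
   field data.

## Worked example

Simulate GPS tracks at the default study conditions, fit the speed
mixture, and fit the raft-size model:

```r
library(raftr)

cfg <- sim_config(n_birds = 8, hours_per_bird = 24)
sim <- simulate_tracks(cfg, seed = 42)
seg <- filter_speed_errors(compute_speeds(sim$fixes))
fit_speed_mixture(seg$speed_ms[!seg$excluded], seed = 42)
#> Two-component normal speed mixture (EM fit)
#>   component 1 (slow): mu = 0.996, sd = 0.492, weight = 0.873
#>   component 2 (fast): mu = 8.804, sd = 2.597, weight = 0.127
#>   logLik -2969.83 after 15 iterations (converged)
#>   equal-posterior threshold: 2.745 m/s
```

The slow component is rafting (~1 m/s drift with wind and tide), the fast
one flight (~9 m/s); birds spend ~87% of segments rafting, and speeds
below the 2.745 m/s equal-posterior threshold are classified as rafting.

```r
d <- simulate_size_series(cfg, seed = 42)
fit_gls_ma(d, q = 4, seed = 42)
#> Generalized least squares: log(raft_size) ~ wind_speed
#> Correlation structure: MA(4) nested within day; REML
#>   AIC 791.8  BIC 816.5  logLik -388.9
#>   theta: 0.049 0.126 0.190 0.307
#>   (Intercept)     4.716 (SE 0.177)  t = 26.691  p = 0.0000  CI [4.368, 5.064]
#>   wind_speed      0.055 (SE 0.018)  t = 3.079  p = 0.0023  CI [0.020, 0.091]
#>   residual SD 1.177 on 249 residual df (n = 251)
```

The positive wind slope means rafts grow with wind speed — each extra m/s
of wind multiplies expected raft size by exp(0.055) ≈ 1.06 — with the
within-day serial correlation absorbed by the four θ parameters.

The full pipeline on a generated input bundle:

```r
paths <- write_fixture_bundle("fixtures", sim_config(), seed = 1)
report <- run_full_analysis(as.list(paths), out_dir = "results", seed = 1)
```

writes georeferenced rafts (GeoJSON + CSV), the classified track CSV, and
`manifest.json` with the headline numbers, all recomputable from the
per-record outputs.

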