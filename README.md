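# decatr

Simulation and analysis of single-molecule DNA braid decatenation traces.

## The problem

In magnetic-tweezers decatenation assays, two DNA tethers anchored to one
paramagnetic bead are intertwined by magnet rotation into a braid that
mimics catenated DNA. A type IA topoisomerase (e.g. *E. coli*
topoisomerase I or III) removes crossings one catenane at a time through
enzyme-bridged strand passage — two catalytic cycles per catenane — and
every removal lengthens the tether by a geometric increment. The raw data
are bead-extension time series at 50 Hz: a braiding ramp down, then a
noisy staircase back up, with bursts of releases ("runs") separated by
exponential pauses.

`decatr` is for people who work with (or want to benchmark methods for)
such traces. It provides:

* **Braid geometry** — the crossover angle from the extension-rotation
  peak, `beta = 2 acos((l - h)/l)`; a piecewise-linear extension-vs-`Ca`
  model and its inverse (displacement → released turns); equipartition
  force calibration `F = kB T <z> / var(x)`.
* **A stochastic simulator** — event schedules (exponential initial and
  secondary lags, shifted-geometric run sizes, exponential intra-run
  intervals; substrate-dependent activity: intact silent, nicked ~10%
  sporadically active, bulge-carrying robust) rendered into 50-Hz traces
  with AR(1) bead noise, full braiding/re-braiding protocol included.
* **The measurement pipeline** — 50-sample running average, two-stage
  step detection (matched-window flagging + binary-segmentation
  localization + persistent-level confirmation), run assembly at a 1-s
  pause resolution, and extraction of the five kinetic features: initial
  time lag, secondary time lags, catenanes per run, rate per run, total
  decatenation rate.
* **Cohort statistics** — exponential dwell-time histogram fits
  (`A e^{-t/t1}`, weighted least squares with counting errors), pooled
  Student's t comparisons, and bimodal crossover-angle classification
  (exact 1-D two-means split with a 10° leave-one-out discard rule).

Everything takes and returns tibbles, so analyses compose with the pipe;
results have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a small topoisomerase III cohort on bulge-carrying braids and
recover its kinetics end to end:

```r
library(decatr)

geom <- braid_geometry(l = 2.3, beta = 47)
geom
#> <braid_geometry> l = 2.300 um, h = 0.1908 um (beta = 47.0 deg), delta = 0.0230 um/turn, ca_max = 50

camp <- run_campaign(12, enzyme = "topoIII", substrate = "bulge", seed = 1)
camp
#> <decat_campaign> 12 experiments (topoIII, bulge, mixed angle): 620 runs detected, 12/12 active

campaign_summary(camp)
#>   enzyme substrate angle_class       feature estimate   error   n       estimator
#> 1 topoIII     bulge       mixed   initial_lag   38.827 8.43820  36 exponential_fit
#> 2 topoIII     bulge       mixed      run_rate    1.308 0.02112 620      arithmetic
#> 3 topoIII     bulge       mixed      run_size    1.902 0.04802 620      arithmetic
#> 4 topoIII     bulge       mixed secondary_lag   13.403 0.64034 584 exponential_fit
#> 5 topoIII     bulge       mixed    total_rate    0.125 0.00701  33      arithmetic
```

The cohort was generated with a 13-s mean secondary lag, a 48-s mean
initial lag and a mean run size of 1.8; the pipeline recovers 13.4 s,
38.8 s (12 experiments is a small cohort — the initial-lag fit has a
±8 s error) and 1.90. `autoplot()` on a simulated trace shows the raw
and smoothed staircase; `autoplot()` on an exponential fit shows the
dwell-time histogram with its decay curve.

A command-line pipeline (`simulate` / `analyze` / `summarize` / `report`)
is available through `decat_cli()` or the script in `inst/cli/decatr.R`,
driven by a flat YAML config; every artifact is regenerable from
(config, seed).

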