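---
title: "Measuring topoisomerase decatenation kinetics from braid traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring topoisomerase decatenation kinetics from braid traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(decatr)
```

## The experiment this package models

In a magnetic-tweezers decatenation assay, two DNA molecules are anchored
between a glass surface and one paramagnetic bead. Rotating the magnets
winds the two tethers around each other into a braid; the number of
crossings is the catenation number `Ca`, and each added crossing shortens
the bead-surface distance. A type IA topoisomerase (here, *E. coli*
topoisomerase I or III) can remove crossings by enzyme-bridged strand
passage, provided a single-stranded region is available — in practice a
27-nt bulge engineered into each tether. Each catenane removed requires
two catalytic cycles of the enzyme (two cleavage/passage events through a
hemicatenated intermediate), and each removal lengthens the tether by a
geometrically determined increment. The recorded observable is bead
extension versus time at 50 Hz: a braiding ramp down, then a staircase
back up as the enzyme works, with bursts of releases ("runs") separated
by clear pauses.

Five features summarize each experiment:

* **initial time lag** — braid completion to the first detected run;
* **secondary time lags** — pauses between consecutive runs;
* **run sizes** — catenanes removed per run;
* **per-run rates** — catenanes removed per second within a run;
* **total decatenation rate** — all removed catenanes divided by the time
  from braid completion to full decatenation (only defined when the braid
  returns to its relaxed extension).

Lag histograms are well described by a single exponential decay, so lag
cohorts are summarized by the fitted mean of `A * exp(-t / t1)`; run
sizes are not exponential and are summarized by their arithmetic mean.

## Braid geometry

The geometry module is the deterministic core. A braid is described by
the relaxed extension `l`, the height `h` of the sharp peak at `Ca = 0`
in the extension-rotation curve, the per-turn shortening `delta` in the
linear flanks, and a validity limit `ca_max`. The crossover angle between
the strands follows from the peak alone,

$$\beta = 2 \arccos\!\left(\frac{l - h}{l}\right),$$

deliberately ignoring bead curvature and DNA diameter — the angle is used
to classify braids into broad small/large groups, not as precision
geometry. The extension model is `z(0) = l`, `z(±1) = l - h`, and
`z(±Ca) = l - h - (|Ca| - 1) delta` beyond the first turn, clamped at
zero and symmetric in `Ca`.

```{r geometry}
geom <- braid_geometry(l = 2.3, beta = 47)
geom
plot_braid_curve(geom, ca_range = 20)
```

Choices worth recording:

* `delta` defaults to `0.01 * l`. Measured extension-rotation curves have
  visually linear, shallow flanks; a linear model keeps the map from
  displacement to released turns piecewise invertible
  (`delta_ca_from_displacement()`), which is how elongations become
  integer catenane counts.
* `l = 2.3` µm is the extension of a 7.3-kb tether (contour ~2.5 µm) at
  the working force of 2 pN.
* Angle-class geometries: 24° for the small group, 47°/49° for the large
  group — the group means reported for these enzymes.
* Force calibration uses the transverse equipartition relation
  `F = kB T <z> / var(x)` with `kB = 1.3806e-23` J/K
  (`kT = 4.28e-3` pN µm at 310 K).

## The synthetic-data generator

`simulate_schedule()` draws the stochastic event schedule of one
experiment; `render_trace()` turns it into the 50-Hz series an instrument
would record. The generating laws, and what they emulate:

* **Initial and secondary lags** are exponential with means `tau_init`
  and `tau_sec` — the observed lag histograms are single-exponential.
* **Run sizes** are shifted geometric on `{1, 2, ...}` with mean
  `mean_run_size`: the one-parameter maximum-entropy law on the positive
  integers, consistent with runs frequently being a single release. The
  published distributions are explicitly not exponential; only their
  means are constrained, so the specific law is a modelling choice.
* **Intra-run intervals** are exponential with rate `intra_run_rate`,
  set to the published per-run rate (1.0–1.2 releases/s). The *measured*
  per-run rate then emerges from smoothing and segmentation rather than
  being imposed (see "Known biases" below).
* **Activity**: bulge substrates are always active; nicked (bulge-free)
  braids are active in 10% of experiments, with a long initial lag
  (240 s, the middle of the reported 3–5 min) and at most a few releases
  per cycle (cap of 5); intact braids are never active.
* **Protocol**: 30–35 turns per braiding, 2 pN, 37 °C, a 30-s braiding
  ramp (magnet rotation time is not published; the initial-lag clock
  starts at ramp end), re-braiding after 600 s of quiescence, three
  braiding cycles per experiment, and a 90-min per-cycle cutoff.
* **Noise**: stationary AR(1) (Ornstein-Uhlenbeck-like) axial noise,
  sd 20 nm, correlation time 20 ms. No published noise floor exists;
  20 nm at 2 pN makes a one-turn step (23 nm here) resolvable but not
  trivial, matching the qualitative description that single events are
  resolved "in most cases".
* An optional per-experiment `dead_time` (default 0) exists because the
  published overall parameters do not compose into the published total
  rates; it is never enabled in the shipped analyses.

What the generator does **not** emulate: instrument drift, bead sticking,
transient force fluctuations, torque-dependent geometry changes within a
braid, and enzyme-concentration effects (the single-enzyme regime is
assumed). Passing round-trip tests therefore demonstrates that the
measurement pipeline is faithful to this idealization, not that it would
be unbiased on arbitrary real recordings.

```{r trace, fig.height = 3}
trace <- simulate_experiment(enzyme = "topoIII", substrate = "bulge",
                             protocol = decat_protocol(n_cycles = 1,
                                                       rebraid_after_quiescence = 30),
                             seed = 42)
autoplot(trace)
```

## Segmentation

`detect_runs()` implements the measurement procedure:

1. the mandated 50-sample unweighted running average (display and rise
   model);
2. candidate transitions where the difference between adjacent 3-s window
   means exceeds 4.5 robust standard deviations. The scale is re-estimated
   on the quiet baseline after masking candidate regions, because runs and
   ramps inflate a single global MAD on event-dense traces. The threshold
   is calibrated against the null: the maximum of this statistic over a
   90-minute event-free trace is typically 4.0–4.6 SD, so a 3-SD cut on
   this statistic would flag noise excursions on nearly every trace;
3. within each candidate region, individual steps are localized by
   least-squares binary segmentation of the raw samples (minimum segment
   5 samples, minimum step half a turn, Welch statistic ≥ 5) — a
   change-point formulation of the velocity-threshold idea;
4. every candidate step must be **confirmed** by a persistent level shift:
   medians over up to 10-s flanking windows (clipped at neighbouring steps
   and braiding ramps) must differ by at least half a turn. This is what
   separates a genuine release (which shifts the level for good) from a
   rare threshold excursion (which does not); without it, roughly one in
   ten event-free 90-min traces grows a spurious one-turn run;
5. steps whose intervening plateau — as observable after smoothing, i.e.
   the true gap minus the 1-s rise time — is shorter than the 1-s pause
   resolution are merged into one run ("a pause that cannot be observed");
6. run elongations are converted to catenanes through the braid geometry
   using wide-flank levels and rounded to integers; candidates rounding
   to zero are discarded as noise.

Braiding ramps are detected as falling regions of the same statistic;
the ramp end (braid completion, the zero of the lag clock) is localized
by a level crossing corrected for the crossing threshold via the local
ramp slope, which is exact on noiseless traces and accurate to ~0.3 s
under the default noise.

Run bookkeeping distinguishes two time conventions deliberately. Run
*event times* (`start_s`, `last_release_s`) are smoothing-corrected
estimates of the first and last release, exact to one sample on noiseless
traces; lags are computed from these, so lag estimates carry no rise-time
offset. Run *durations* (`end_s - start_s`) are rise-inclusive — the last
release plus the 1-s smoothing rise — because that is what an observer
measures on the smoothed trace, and it keeps `rate = delta_ca / duration`
well defined for single-release runs (which have zero event-time span).

## Cohort statistics

`fit_exponential_histogram()` reproduces the histogram-fit procedure:
values binned from zero (default bin width `max/8`), weighted least
squares of `A exp(-t/t1)` on the counts with square-root counting errors,
`t1` reported with its fit standard error. Maximum likelihood (the sample
mean) is available as `method = "mle"` and serves as the cross-check in
the tests. `summarize_cohort()` applies the exponential fit to lags and
the arithmetic mean to run sizes — and also to per-run and total rates:
an exponential decay is only a meaningful model for monotonically
decaying dwell histograms, and the simulated rate distributions are
sharply peaked (see below), so a decay fit to them is ill-posed. This is
the one deliberate departure from the convention of fitting rates.

`classify_crossover_angles()` splits measured angles at the exact 1-D
two-means optimum (exhaustive over sorted split points) and then
iteratively discards angles more than 10° from the mean of the *rest* of
their group. The leave-one-out form matters: a single outlier drags the
including-mean toward itself and can sit within 10° of it while being
13° from every other member.

`compare_groups()` is the pooled-variance two-sided Student's t test,
with the convention P = 1 for two identical constant samples.

## Known biases of the round trip

The pipeline is validated by parameter recovery: configure the generator
with the published kinetic parameters, render noisy traces, analyze them,
and compare the recovered cohort statistics with the generating values.
Three systematic effects, all consequences of the 1-s rise time and pause
resolution, are worth knowing:

* **Sub-resolution pauses censor the lag distributions.** Pauses whose
  observable plateau is shorter than 1 s merge their flanking runs, and
  intra-run gaps longer than that split a run in two. The surviving lag
  sample is a shifted exponential plus a small contamination of short
  split-gaps; because an exponential is memoryless these effects nearly
  cancel in the fitted mean, leaving a few-percent bias (upward for short
  generating means, downward when contamination dominates).
* **Run sizes are biased a few percent.** Splitting long intra-run gaps
  shrinks runs (topoisomerase I conditions, about −7%), merging short
  inter-run pauses grows them (topoisomerase III conditions, about +3%).
* **Per-run rates are inflated about 20%.** A single release has no
  intrinsic duration; it is assigned the 1-s smoothing rise, giving
  exactly 1 turn/s. Unresolved bursts (two releases within the rise
  time) are assigned 2 turns/s, and splitting censors the slowest runs.
  Generating at the published 1.0–1.2 /s therefore yields measured means
  near 1.2–1.3 /s. We report the faithful arithmetic mean rather than
  adjusting the generator or the estimator to cancel this.

Total decatenation rates are validated against simulator ground truth
(per-cycle agreement to a few percent) rather than against the published
overall values, which are not mutually consistent with composing the
other four published parameters over a 30–35-turn braid.

## Cohort sizes and runtime

The shipped validation uses desk-scale cohorts chosen so that statistical
error is comfortably below the systematic effects above: 200 experiments
(600 braiding cycles) per enzyme for the overall conditions, 100 per
angle class, and 1000 single-cycle 90-min experiments for the nicked
substrate. A 100-experiment cohort simulates and analyzes in about a
minute on one core; the full validation script takes a few minutes.

## A worked round trip

```{r roundtrip}
camp <- run_campaign(12, enzyme = "topoIII", substrate = "bulge", seed = 1)
campaign_summary(camp)
```

The secondary-lag estimate should sit near the generating 13 s, the run
size near 1.8, and the initial lag near 48 s, within the (small-cohort)
errors shown.

## Limitations

* The extension model is piecewise linear; real braid curves flatten
  near full catenation and the Ca = 1 peak height depends on force.
* Negative (left-handed) braids are not modelled.
* The segmentation assumes stationary noise and a stable baseline; real
  drift would need detrending before these thresholds are trustworthy.
* Torque is not modelled at all: the crossover angle enters only as a
  geometric label for grouping, not as a mechanistic variable.
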