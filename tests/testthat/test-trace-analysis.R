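# Segmentation and feature extraction.

test_that("running average is centred, length-preserving and exact on ramps", {
  expect_equal(running_average(rep(3, 100), 50), rep(3, 100))
  x <- rnorm(20)
  expect_equal(running_average(x, 1), x)
  ramp <- seq(0, 10, length.out = 500)
  sm <- running_average(ramp, 51)
  # moving mean of an affine series is the series away from the edges
  expect_equal(sm[26:475], ramp[26:475], tolerance = 1e-12)
  expect_error(running_average(numeric(0)), "empty")
  expect_error(running_average(1:10, 11), "window")
})

test_that("noiseless staircases are segmented exactly", {
  g <- test_geom()
  tr <- braided_staircase_trace(g, turns = 20,
                                step_times = c(100, 160, 230),
                                duration = 300)
  runs <- detect_runs(tr, g)
  expect_identical(nrow(runs), 3L)
  expect_equal(runs$delta_ca, c(1, 1, 1))
  expect_equal(runs$start_s, c(100, 160, 230), tolerance = 0.03)
  expect_equal(runs$last_release_s, c(100, 160, 230), tolerance = 0.03)
})

test_that("rises separated by sub-resolution plateaus merge into one run", {
  g <- test_geom()
  # two releases 0.2 s apart: a single run of 2
  tr <- detect_runs(braided_staircase_trace(g, 20, c(100, 100.2),
                                            duration = 200), g)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$delta_ca, 2)
  # 2.5 s apart: observable plateau 1.5 s >= resolution, two runs
  tr2 <- detect_runs(braided_staircase_trace(g, 20, c(100, 102.5),
                                             duration = 200), g)
  expect_identical(nrow(tr2), 2L)
  expect_equal(tr2$delta_ca, c(1, 1))
})

test_that("event-free noisy traces yield no false runs across 100 seeds", {
  g <- test_geom()
  total_fp <- 0L
  for (s in 1:100) {
    tr <- braided_staircase_trace(g, turns = 32, step_times = 250,
                                  sizes = 0, duration = 300,
                                  sigma = 0.02, seed = s)
    total_fp <- total_fp + nrow(detect_runs(tr, g))
  }
  expect_identical(total_fp, 0L)
})

test_that("segmentation is invariant to a constant extension offset", {
  g <- test_geom()
  tr <- braided_staircase_trace(g, 25, c(120, 180), sizes = c(2, 1),
                                duration = 260, sigma = 0.02, seed = 3)
  r1 <- detect_runs(tr, g)
  tr2 <- tr
  tr2$extension_um <- tr2$extension_um - 0.05
  r2 <- detect_runs(tr2, g)
  expect_equal(r1$start_s, r2$start_s)
  expect_equal(r1$delta_ca, r2$delta_ca)
})

test_that("geometry inconsistent with the trace is an analysis error", {
  g <- test_geom()
  tr <- braided_staircase_trace(g, 20, 100, duration = 200)
  small <- braid_geometry(l = 1.2, beta = 47)
  expect_error(detect_runs(tr, small), "exceed")
})

test_that("noiseless pipeline reproduces the generating schedule", {
  pc <- preset_condition("topoIII", "bulge")
  prot <- decat_protocol(n_cycles = 2)
  set.seed(21)
  tr <- simulate_experiment(pc$params, pc$geom, prot, noise_model(0, 0))
  sched <- trace_metadata(tr)$schedule
  runs <- detect_runs(tr)
  # all releases recovered, never more than applied
  expect_equal(sum(runs$delta_ca), nrow(sched$events))
  for (c in sched$cycles$cycle) {
    expect_lte(sum(runs$delta_ca[runs$cycle == c]),
               sched$cycles$turns[sched$cycles$cycle == c])
  }
  # every detected run boundary coincides with a true release time;
  # sub-resolution bursts localize their merged step to within a few
  # samples of the constituent releases
  dt <- 1 / prot$sample_rate
  for (k in seq_len(nrow(runs))) {
    expect_lt(min(abs(sched$events$time_s - runs$start_s[k])), 5 * dt)
    expect_lt(min(abs(sched$events$time_s - runs$last_release_s[k])), 5 * dt)
  }
  # lags agree with the schedule: secondary lags are inter-release gaps
  fe <- extract_summary(runs, applied_turns = sched$cycles$turns)
  cyc <- attr(runs, "cycles")
  for (c in unique(runs$cycle)) {
    truth_init <- sched$events$time_s[sched$events$cycle == c][1] -
      sched$cycles$braid_done_s[c]
    got_init <- fe$value[fe$feature == "initial_lag" & fe$cycle == c]
    expect_equal(got_init, truth_init, tolerance = 0.5)
  }
  # full decatenation time matches to one sample
  expect_equal(cyc$full_decat_s,
               sched$cycles$full_decat_s, tolerance = 2 * dt)
})

test_that("feature extraction follows the lag and rate definitions", {
  runs <- tibble::tibble(
    cycle = c(1L, 1L), run = c(1L, 2L),
    start_s = c(100, 150), end_s = c(102, 151),
    last_release_s = c(102, 151) - 1, # rise-inclusive ends
    dz_um = c(0.046, 0.023), delta_ca = c(2, 1),
    rate_ca_s = c(2 / 2, 1 / 1), level_after_um = c(2.28, 2.30)
  )
  runs$last_release_s <- c(101, 150.2)
  cycles <- tibble::tibble(
    cycle = 1L, completion_s = 60, post_level_um = 2.23,
    pre_level_um = 2.3, applied_turns_est = 3, relaxed_level_um = 2.3,
    full_decat_s = 150.2, n_released = 3
  )
  fe <- extract_summary(runs, cycles, applied_turns = 3)
  expect_equal(fe$value[fe$feature == "initial_lag"], 40)
  expect_equal(fe$value[fe$feature == "secondary_lag"], 150 - 101)
  expect_equal(sort(fe$value[fe$feature == "run_size"]), c(1, 2))
  expect_equal(fe$value[fe$feature == "total_rate"], 3 / (150.2 - 60),
               tolerance = 1e-12)
  # undetected turns: total rate withheld
  fe2 <- extract_summary(runs, cycles, applied_turns = 5)
  expect_identical(sum(fe2$feature == "total_rate"), 0L)
  # single run releasing everything: no secondary lags
  fe3 <- extract_summary(runs[1, ], cycles, applied_turns = 2)
  expect_identical(sum(fe3$feature == "secondary_lag"), 0L)
  # overlapping runs are rejected
  bad <- runs
  bad$start_s[2] <- 100.5
  expect_error(extract_summary(bad, cycles), "overlap")
})

test_that("braid QC accepts symmetric braid curves and rejects pathologies", {
  g <- test_geom()
  curves <- dplyr::bind_rows(
    dplyr::mutate(braid_curve(g, ca_range = 15), force_pn = 2.0),
    dplyr::mutate(braid_curve(g, ca_range = 15), force_pn = 0.5)
  )
  qc <- qc_select_braid(curves, relaxed_extensions = c(2.30, 2.32))
  expect_true(qc$accept)
  # supercoiled single tether: asymmetric, rejected with the symmetry flag
  qc2 <- qc_select_braid(supercoil_hat_curve(), c(2.30, 2.32))
  expect_false(qc2$accept)
  expect_true("asymmetric_curve" %in% qc2$flags)
  # matching curves but mismatched relaxed extensions
  qc3 <- qc_select_braid(curves, c(2.1, 2.32))
  expect_false(qc3$accept)
  expect_true("relaxed_extension_mismatch" %in% qc3$flags)
  # non-symmetric grid is an input error
  expect_error(qc_select_braid(tibble::tibble(ca = 0:5, extension_um = 2),
                               c(2.3, 2.3)), "symmetric")
})
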