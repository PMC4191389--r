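# Stochastic generator: sampling laws, schedule invariants, rendering.

test_that("pause sampler follows its exponential law", {
  set.seed(11)
  x <- sample_pause(13, n = 1e5)
  expect_equal(mean(x), 13, tolerance = 0.1 / 13 * 3)
  expect_equal(mean(x <= 13), 1 - exp(-1), tolerance = 0.01)
  ks <- suppressWarnings(ks.test(x, "pexp", rate = 1 / 13))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_pause(0), "positive")
})

test_that("run-size sampler is shifted geometric with the right mean", {
  expect_true(all(sample_run_size(1, n = 100) == 1L))
  set.seed(12)
  x <- sample_run_size(1.8, n = 1e5)
  expect_true(all(x >= 1))
  expect_equal(mean(x), 1.8, tolerance = 0.015)
  expect_equal(mean(x == 1), 1 / 1.8, tolerance = 0.015)
  # full distributional check against the geometric law
  chi <- chisq.test(table(pmin(x, 8)),
                    p = c(dgeom(0:6, 1 / 1.8), pgeom(6, 1 / 1.8, lower.tail = FALSE)))
  expect_gt(chi$p.value, 0.01)
  expect_error(sample_run_size(0.5), ">= 1")
})

test_that("schedules respect turn budgets, ordering and the two-cycles-per-catenane tally", {
  pc <- preset_condition("topoIII", "bulge")
  prot <- decat_protocol(n_cycles = 2)
  set.seed(5)
  for (i in 1:20) {
    s <- simulate_schedule(pc$params, prot, "bulge")
    expect_true(all(diff(s$events$time_s[order(s$events$time_s)]) > 0))
    for (c in s$cycles$cycle) {
      ev <- s$events[s$events$cycle == c, ]
      expect_lte(nrow(ev), s$cycles$turns[s$cycles$cycle == c])
      if (nrow(ev)) expect_true(all(ev$time_s > s$cycles$braid_done_s[c]))
    }
    expect_identical(s$catalytic_cycles, 2L * nrow(s$events))
  }
})

test_that("intact substrate never shows activity; activity_prob = 0 gives no events", {
  pc <- preset_condition("topoIII", "intact")
  set.seed(6)
  for (i in 1:10) {
    s <- simulate_schedule(pc$params, decat_protocol(n_cycles = 1), "intact")
    expect_identical(nrow(s$events), 0L)
  }
  p0 <- kinetic_params(10, 10, 1.5, 1, activity_prob = 0)
  s <- simulate_schedule(p0, decat_protocol(n_cycles = 1), "bulge")
  expect_identical(nrow(s$events), 0L)
})

test_that("mean first-run start matches the generating initial lag", {
  pc <- preset_condition("topoIII", "bulge")
  prot <- decat_protocol(n_cycles = 1)
  set.seed(8)
  lags <- replicate(500, {
    s <- simulate_schedule(pc$params, prot, "bulge")
    s$events$time_s[1] - s$cycles$braid_done_s[1]
  })
  se <- pc$params$tau_init / sqrt(500)
  expect_lt(abs(mean(lags) - pc$params$tau_init), 2 * se + 1e-9)
})

test_that("noiseless rendering is the exact extension staircase", {
  pc <- preset_condition("topoIII", "bulge")
  prot <- decat_protocol(n_cycles = 1)
  set.seed(9)
  sched <- simulate_schedule(pc$params, prot, "bulge")
  tr <- render_trace(sched, pc$geom, noise_model(0, 0), prot)
  turns <- sched$cycles$turns[1]
  # after the ramp, the level at any time equals extension at the current Ca
  probe <- sched$events$time_s + 0.5
  for (k in seq_along(probe)) {
    i <- findInterval(probe[k], tr$time_s)
    ca_true <- turns - sum(sched$events$time_s <= tr$time_s[i])
    expect_equal(tr$extension_um[i], braid_extension(pc$geom, ca_true),
                 tolerance = 1e-12)
  }
  # a single 1-turn release in the linear regime moves the level by delta
  ev1 <- sched$events$time_s[1]
  i_pre <- findInterval(ev1 - 0.1, tr$time_s)
  i_post <- findInterval(ev1 + 0.1, tr$time_s)
  expect_equal(tr$extension_um[i_post] - tr$extension_um[i_pre],
               pc$geom$delta, tolerance = 1e-12)
})

test_that("rendered noise is zero-mean with the configured sd", {
  pc <- preset_condition("topoIII", "intact")
  prot <- decat_protocol(n_cycles = 1, max_wait = 300,
                         rebraid_after_quiescence = 10)
  set.seed(10)
  sched <- simulate_schedule(pc$params, prot, "intact")
  tr0 <- render_trace(sched, pc$geom, noise_model(0, 0), prot)
  tr <- render_trace(sched, pc$geom, noise_model(0.02, 0.02), prot)
  resid <- tr$extension_um - tr0$extension_um
  expect_lt(abs(mean(resid)), 3 * 0.02 / sqrt(length(resid) / 3))
  expect_equal(sd(resid), 0.02, tolerance = 0.1)
})

test_that("campaigns are bit-reproducible from their seed", {
  prot <- decat_protocol(n_cycles = 1, max_wait = 200,
                         rebraid_after_quiescence = 10)
  c1 <- simulate_campaign(3, protocol = prot, enzyme = "topoIII",
                          substrate = "bulge", seed = 123)
  c2 <- simulate_campaign(3, protocol = prot, enzyme = "topoIII",
                          substrate = "bulge", seed = 123)
  for (i in 1:3) {
    expect_identical(c1[[i]]$extension_um, c2[[i]]$extension_um)
  }
})

test_that("nicked campaigns show the configured active fraction", {
  pc <- preset_condition("topoIII", "nicked")
  set.seed(14)
  active <- replicate(400, {
    s <- simulate_schedule(pc$params, decat_protocol(n_cycles = 1), "nicked")
    nrow(s$events) > 0
  })
  se <- sqrt(0.1 * 0.9 / 400)
  expect_lt(abs(mean(active) - 0.10), 3 * se)
})
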