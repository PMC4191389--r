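# Kinetic scheme of enzyme-driven decatenation and the experiment protocol.
#
# A braiding cycle is modelled as: exponential initial lag after braid
# completion, then alternating runs and exponential inter-run pauses. A run
# removes a shifted-geometric number of catenanes, one per release, with
# exponential intra-run intervals. The release of one catenane is tallied as
# two catalytic cycles of a type IA topoisomerase (enzyme-bridged strand
# passage through a hemicatenated intermediate needs two cleavages).

#' Kinetic parameters of a decatenation enzyme/substrate pair
#'
#' @param tau_init Mean initial time lag (s): braid completion to first run.
#' @param tau_sec Mean secondary time lag (s): pause between runs.
#' @param mean_run_size Mean catenanes removed per run (turns, `>= 1`); run
#'   sizes are drawn from a shifted geometric law on `{1, 2, ...}`.
#' @param intra_run_rate Catenane releases per second within a run (1/s).
#' @param activity_prob Probability that an experiment shows any activity.
#' @param release_cap Maximum catenanes released per braiding cycle
#'   (default unlimited); models substrates supporting only sporadic, weak
#'   activity.
#' @param dead_time Fixed unobserved dead time (s) added to the initial lag
#'   of every cycle; default 0.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(tau_init, tau_sec, mean_run_size, intra_run_rate,
                           activity_prob = 1, release_cap = Inf,
                           dead_time = 0) {
  for (nm in c("tau_init", "tau_sec", "intra_run_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number.", nm), call. = FALSE)
    }
  }
  if (mean_run_size < 1) stop("`mean_run_size` must be >= 1.", call. = FALSE)
  if (activity_prob < 0 || activity_prob > 1) {
    stop("`activity_prob` must lie in [0, 1].", call. = FALSE)
  }
  if (dead_time < 0) stop("`dead_time` must be non-negative.", call. = FALSE)
  structure(
    list(tau_init = tau_init, tau_sec = tau_sec,
         mean_run_size = mean_run_size, intra_run_rate = intra_run_rate,
         activity_prob = activity_prob, release_cap = release_cap,
         dead_time = dead_time),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    paste0("<kinetic_params> tau_init = %g s, tau_sec = %g s, ",
           "mean run size = %g, intra-run rate = %g /s, activity = %g\n"),
    x$tau_init, x$tau_sec, x$mean_run_size, x$intra_run_rate, x$activity_prob
  ))
  invisible(x)
}

#' Experiment protocol
#'
#' Instrument and protocol settings of a braiding/decatenation experiment.
#' Defaults reproduce the conditions of the experiments this package
#' emulates: 30-35 positive turns, 2.0 pN, 50 Hz sampling, 37 C, re-braiding
#' 10 min after decatenation ceases.
#'
#' @param turns_min,turns_max Applied turns are drawn uniformly from this
#'   integer range at every braiding.
#' @param force Stretching force (pN).
#' @param sample_rate Sampling rate (Hz).
#' @param temperature Temperature (K).
#' @param max_wait Per-cycle observation cutoff (s) if decatenation does not
#'   complete.
#' @param rebraid_after_quiescence Quiescent time after a cycle before the
#'   braid is re-formed (s).
#' @param ramp_duration Duration of the braiding ramp (s); magnet rotation
#'   is not instantaneous. The initial-lag clock starts at ramp end.
#' @param n_cycles Braiding cycles per experiment.
#' @param lead_in Relaxed hold before the first braiding (s).
#' @return An object of class `decat_protocol`.
#' @export
decat_protocol <- function(turns_min = 30, turns_max = 35, force = 2.0,
                           sample_rate = 50, temperature = 310,
                           max_wait = 5400, rebraid_after_quiescence = 600,
                           ramp_duration = 30, n_cycles = 3, lead_in = 10) {
  if (turns_min < 1 || turns_max < turns_min) {
    stop("Need 1 <= turns_min <= turns_max.", call. = FALSE)
  }
  if (sample_rate <= 0) stop("`sample_rate` must be positive.", call. = FALSE)
  if (max_wait <= 0) stop("`max_wait` must be positive.", call. = FALSE)
  if (n_cycles < 1) stop("`n_cycles` must be at least 1.", call. = FALSE)
  structure(
    list(turns_min = as.integer(turns_min), turns_max = as.integer(turns_max),
         force = force, sample_rate = sample_rate, temperature = temperature,
         max_wait = max_wait,
         rebraid_after_quiescence = rebraid_after_quiescence,
         ramp_duration = ramp_duration, n_cycles = as.integer(n_cycles),
         lead_in = lead_in),
    class = "decat_protocol"
  )
}

#' Bead noise model
#'
#' First-order autoregressive (exponentially correlated) Gaussian noise on
#' the axial bead coordinate. `corr_time = 0` gives white noise.
#'
#' @param sigma_z Stationary standard deviation of the axial noise
#'   (micrometres).
#' @param corr_time Correlation time (s).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_z = 0.02, corr_time = 0.02) {
  if (sigma_z < 0) stop("`sigma_z` must be non-negative.", call. = FALSE)
  if (corr_time < 0) stop("`corr_time` must be non-negative.", call. = FALSE)
  structure(list(sigma_z = sigma_z, corr_time = corr_time),
            class = "noise_model")
}

#' Reference kinetic parameter sets
#'
#' Published single-molecule kinetic parameters for decatenation of braided
#' 7.3-kb DNA tethers carrying 27-nt bulges by E. coli topoisomerases I and
#' III at 2 pN, overall and split by crossover-angle class, together with
#' the default activity model for nicked (bulge-free) and intact braids.
#' These are the generating values used when simulating a named condition.
#'
#' @return A tibble with one row per enzyme/substrate/angle-class condition
#'   and columns `enzyme`, `substrate`, `angle_class`, `tau_init_s`,
#'   `tau_sec_s`, `mean_run_size`, `intra_run_rate_s`, `activity_prob`,
#'   `release_cap`, `beta_deg`.
#' @export
kinetic_presets <- function() {
  tibble::tribble(
    ~enzyme,   ~substrate, ~angle_class, ~tau_init_s, ~tau_sec_s, ~mean_run_size, ~intra_run_rate_s, ~activity_prob, ~release_cap, ~beta_deg,
    "topoI",   "bulge",    "mixed",      33,          43,         1.7,            1.0,               1.0,            Inf,          47,
    "topoIII", "bulge",    "mixed",      48,          13,         1.8,            1.2,               1.0,            Inf,          47,
    "topoI",   "bulge",    "small",      53,          27,         1.7,            1.0,               1.0,            Inf,          24,
    "topoI",   "bulge",    "large",      54,          43,         1.7,            1.0,               1.0,            Inf,          49,
    "topoIII", "bulge",    "small",      41,          45,         1.9,            0.9,               1.0,            Inf,          24,
    "topoIII", "bulge",    "large",      41,           9,         1.7,            1.1,               1.0,            Inf,          47,
    "topoI",   "nicked",   "mixed",      240,         43,         1.5,            1.0,               0.10,           5,            47,
    "topoIII", "nicked",   "mixed",      240,         43,         1.5,            1.0,               0.10,           5,            47,
    "topoI",   "intact",   "mixed",      240,         43,         1.5,            1.0,               0.0,            0,            47,
    "topoIII", "intact",   "mixed",      240,         43,         1.5,            1.0,               0.0,            0,            47
  )
}

#' Look up a preset condition
#'
#' @param enzyme `"topoI"` or `"topoIII"`.
#' @param substrate `"bulge"`, `"nicked"` or `"intact"`.
#' @param angle_class `"mixed"` (overall), `"small"` or `"large"`; only the
#'   bulge substrate is split by angle.
#' @return A list with elements `params` (a [kinetic_params()]) and `geom`
#'   (a [braid_geometry()] whose crossover angle matches the class).
#' @export
preset_condition <- function(enzyme = c("topoI", "topoIII"),
                             substrate = c("bulge", "nicked", "intact"),
                             angle_class = c("mixed", "small", "large")) {
  enzyme <- match.arg(enzyme)
  substrate <- match.arg(substrate)
  angle_class <- match.arg(angle_class)
  if (substrate != "bulge") angle_class <- "mixed"
  tab <- kinetic_presets()
  row <- tab[tab$enzyme == enzyme & tab$substrate == substrate &
               tab$angle_class == angle_class, ]
  if (nrow(row) != 1L) {
    stop("No preset for this enzyme/substrate/angle-class combination.",
         call. = FALSE)
  }
  params <- kinetic_params(
    tau_init = row$tau_init_s, tau_sec = row$tau_sec_s,
    mean_run_size = row$mean_run_size, intra_run_rate = row$intra_run_rate_s,
    activity_prob = if (substrate == "intact") 0 else row$activity_prob,
    release_cap = row$release_cap
  )
  geom <- braid_geometry(l = 2.3, beta = row$beta_deg, ca_max = 50)
  list(params = params, geom = geom, enzyme = enzyme, substrate = substrate,
       angle_class = angle_class)
}

#' Draw an exponential pause
#'
#' @param mean Mean pause duration (s), positive.
#' @param n Number of draws.
#' @return Exponential variate(s) with the given mean.
#' @export
sample_pause <- function(mean, n = 1) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0) {
    stop("`mean` must be a single positive number.", call. = FALSE)
  }
  stats::rexp(n, rate = 1 / mean)
}

#' Draw a run size
#'
#' Shifted geometric law on `{1, 2, 3, ...}` with success probability
#' `1 / mean_run_size`, so the expectation equals `mean_run_size`. This is
#' the one-parameter maximum-entropy law on the positive integers and
#' reproduces the observation that runs are often a single catenane release.
#'
#' @param mean_run_size Mean run size (`>= 1`).
#' @param n Number of draws.
#' @return Integer run size(s), each `>= 1`.
#' @export
sample_run_size <- function(mean_run_size, n = 1) {
  if (!is.numeric(mean_run_size) || length(mean_run_size) != 1L ||
      !is.finite(mean_run_size) || mean_run_size < 1) {
    stop("`mean_run_size` must be a single number >= 1.", call. = FALSE)
  }
  1L + stats::rgeom(n, prob = 1 / mean_run_size)
}

#' Simulate an event schedule
#'
#' Draws the full stochastic event schedule of one experiment: per braiding
#' cycle, an initial exponential lag, then alternating runs (shifted
#' geometric size, exponential intra-run release intervals) and exponential
#' inter-run pauses, until the braid is fully decatenated, the per-cycle
#' release cap is hit, or `max_wait` elapses. With probability
#' `1 - activity_prob` (and always for intact substrates) the experiment is
#' inactive and contains no events.
#'
#' @param params A [kinetic_params()].
#' @param protocol A [decat_protocol()].
#' @param substrate `"bulge"`, `"nicked"` or `"intact"`; intact forces zero
#'   activity.
#' @return An object of class `event_schedule`: a list with
#'   * `cycles`: tibble with one row per braiding cycle (`cycle`,
#'     `braid_start_s`, `braid_done_s`, `turns`, `n_released`,
#'     `full_decat_s` (`NA` if not reached), `cycle_end_s`),
#'   * `events`: tibble of catenane releases (`cycle`, `run`, `time_s`),
#'     one row per released catenane,
#'   * `active`: logical,
#'   * `catalytic_cycles`: `2 *` total releases.
#' @export
simulate_schedule <- function(params, protocol = decat_protocol(),
                              substrate = "bulge") {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(protocol, "decat_protocol"))
  substrate <- match.arg(substrate, c("bulge", "nicked", "intact"))
  active <- substrate != "intact" &&
    stats::runif(1) < params$activity_prob

  cycles <- vector("list", protocol$n_cycles)
  events <- vector("list", protocol$n_cycles)
  t_cursor <- protocol$lead_in
  for (cyc in seq_len(protocol$n_cycles)) {
    turns <- sample(seq(protocol$turns_min, protocol$turns_max), 1L)
    braid_start <- t_cursor
    braid_done <- braid_start + protocol$ramp_duration
    remaining <- turns
    released <- 0L
    ev_time <- numeric(0)
    ev_run <- integer(0)
    run_idx <- 0L
    full_decat <- NA_real_
    if (active) {
      t <- braid_done + params$dead_time + sample_pause(params$tau_init)
      cap <- min(turns, params$release_cap)
      while (released < cap && t <= braid_done + protocol$max_wait) {
        run_idx <- run_idx + 1L
        size <- min(sample_run_size(params$mean_run_size), cap - released)
        gaps <- if (size > 1L) sample_pause(1 / params$intra_run_rate, size - 1L) else numeric(0)
        times <- t + cumsum(c(0, gaps))
        times <- times[times <= braid_done + protocol$max_wait]
        if (length(times) == 0L) break
        ev_time <- c(ev_time, times)
        ev_run <- c(ev_run, rep(run_idx, length(times)))
        released <- released + length(times)
        if (released >= turns) {
          full_decat <- times[length(times)]
          break
        }
        t <- times[length(times)] + sample_pause(params$tau_sec)
      }
    }
    cycle_end <- if (!is.na(full_decat)) full_decat else braid_done + protocol$max_wait
    cycle_end <- cycle_end + protocol$rebraid_after_quiescence
    cycles[[cyc]] <- tibble::tibble(
      cycle = cyc, braid_start_s = braid_start, braid_done_s = braid_done,
      turns = turns, n_released = released, full_decat_s = full_decat,
      cycle_end_s = cycle_end
    )
    events[[cyc]] <- tibble::tibble(
      cycle = rep(cyc, length(ev_time)), run = ev_run, time_s = ev_time
    )
    t_cursor <- cycle_end
  }
  cycles <- dplyr::bind_rows(cycles)
  events <- dplyr::bind_rows(events)
  structure(
    list(cycles = cycles, events = events, active = active,
         catalytic_cycles = 2L * nrow(events),
         params = params, protocol = protocol, substrate = substrate),
    class = "event_schedule"
  )
}

#' @export
print.event_schedule <- function(x, ...) {
  cat(sprintf(
    "<event_schedule> %d cycle(s), %d release(s) (%s), %d catalytic cycles\n",
    nrow(x$cycles), nrow(x$events),
    if (x$active) "active" else "inactive", x$catalytic_cycles
  ))
  invisible(x)
}

#' Simulate one experiment (schedule + rendered trace)
#'
#' @param params A [kinetic_params()]; if `NULL`, taken from
#'   [preset_condition()] for `enzyme`/`substrate`/`angle_class`.
#' @param geom A [braid_geometry()]; preset-derived if `NULL`.
#' @param protocol A [decat_protocol()].
#' @param noise A [noise_model()].
#' @param enzyme,substrate,angle_class Condition labels (and preset lookup
#'   keys when `params`/`geom` are not given).
#' @param seed Optional integer seed for reproducibility.
#' @return A `decat_trace` tibble (see [render_trace()]) with the generating
#'   schedule embedded in its metadata.
#' @export
simulate_experiment <- function(params = NULL, geom = NULL,
                                protocol = decat_protocol(),
                                noise = noise_model(),
                                enzyme = "topoIII", substrate = "bulge",
                                angle_class = "mixed", seed = NULL) {
  if (is.null(params) || is.null(geom)) {
    preset <- preset_condition(enzyme, substrate, angle_class)
    if (is.null(params)) params <- preset$params
    if (is.null(geom)) geom <- preset$geom
  }
  if (!is.null(seed)) set.seed(seed)
  sched <- simulate_schedule(params, protocol, substrate)
  render_trace(sched, geom, noise, protocol,
               enzyme = enzyme, substrate = substrate,
               angle_class = angle_class, seed = seed)
}

#' Simulate a campaign of experiments
#'
#' Batch harness: repeated experiments under one condition with
#' deterministically derived per-experiment seeds, so a campaign is
#' bit-reproducible from `(condition, seed)` and individual experiments can
#' be regenerated in isolation.
#'
#' @inheritParams simulate_experiment
#' @param n_experiments Number of experiments (`>= 1`).
#' @param seed Campaign seed (integer).
#' @return A list of `decat_trace` objects of length `n_experiments`.
#' @export
simulate_campaign <- function(n_experiments, params = NULL, geom = NULL,
                              protocol = decat_protocol(),
                              noise = noise_model(),
                              enzyme = "topoIII", substrate = "bulge",
                              angle_class = "mixed", seed = 1) {
  stopifnot(n_experiments >= 1)
  purrr::map(seq_len(n_experiments), function(i) {
    simulate_experiment(params, geom, protocol, noise, enzyme, substrate,
                        angle_class, seed = derive_seed(seed, i))
  })
}

# Per-experiment seed derivation: deterministic, collision-free for
# i < 1e6, and below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483629)
}
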