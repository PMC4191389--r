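# Rendering an event schedule into a sampled, noisy extension trace.

#' Render a schedule into a noisy extension trace
#'
#' Produces the uniformly sampled bead-extension time series a magnetic
#' tweezers instrument would record for a given event schedule: a relaxed
#' lead-in, a linear braiding ramp each cycle, piecewise-constant catenation
#' stepping down at the release times (mapped through [braid_extension()]),
#' and additive first-order autoregressive Gaussian noise.
#'
#' @param schedule An [simulate_schedule()] result.
#' @param geom A [braid_geometry()] with `ca_max` at least the applied turns.
#' @param noise A [noise_model()].
#' @param protocol A [decat_protocol()]; defaults to the one stored in the
#'   schedule.
#' @param enzyme,substrate,angle_class Labels carried into the metadata.
#' @param seed Seed recorded in the metadata (not consumed here).
#' @return A `decat_trace`: a tibble with columns `time_s` and
#'   `extension_um` and a `metadata` attribute (list with `geom`,
#'   `protocol`, `noise`, labels, `seed` and the ground-truth `schedule`).
#' @export
render_trace <- function(schedule, geom, noise = noise_model(),
                         protocol = NULL, enzyme = NA_character_,
                         substrate = NULL, angle_class = NA_character_,
                         seed = NA_integer_) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(geom, "braid_geometry"),
            inherits(noise, "noise_model"))
  if (is.null(protocol)) protocol <- schedule$protocol
  if (protocol$sample_rate <= 0) stop("`sample_rate` must be positive.", call. = FALSE)
  if (is.null(substrate)) substrate <- schedule$substrate
  if (geom$ca_max < max(schedule$cycles$turns)) {
    stop("Geometry ca_max is smaller than the applied turns.", call. = FALSE)
  }

  dt <- 1 / protocol$sample_rate
  t_end <- max(schedule$cycles$cycle_end_s)
  times <- seq(0, t_end, by = dt)
  ca <- numeric(length(times))

  for (cyc in seq_len(nrow(schedule$cycles))) {
    cy <- schedule$cycles[cyc, ]
    ev <- schedule$events[schedule$events$cycle == cy$cycle, ]
    idx <- which(times >= cy$braid_start_s & times < cy$cycle_end_s)
    tt <- times[idx]
    # linear ramp from the residual catenation up to the applied turns
    ca_start_ramp <- ca[max(which(times < cy$braid_start_s), 1)]
    ramp <- ca_start_ramp + (cy$turns - ca_start_ramp) *
      pmin(pmax((tt - cy$braid_start_s) / protocol$ramp_duration, 0), 1)
    n_rel <- if (nrow(ev)) findInterval(tt, sort(ev$time_s)) else 0L
    ca[idx] <- ifelse(tt < cy$braid_done_s, ramp, cy$turns - n_rel)
  }

  z <- braid_extension(geom, ca)
  if (noise$sigma_z > 0) {
    eps <- stats::rnorm(length(z))
    if (noise$corr_time > 0) {
      rho <- exp(-dt / noise$corr_time)
      eps <- as.numeric(stats::filter(eps * sqrt(1 - rho^2), rho,
                                      method = "recursive",
                                      init = stats::rnorm(1)))
    }
    z <- z + noise$sigma_z * eps
  }

  out <- tibble::tibble(time_s = times, extension_um = z)
  attr(out, "metadata") <- list(
    geom = geom, protocol = protocol, noise = noise, enzyme = enzyme,
    substrate = substrate, angle_class = angle_class, seed = seed,
    schedule = schedule
  )
  class(out) <- c("decat_trace", class(out))
  out
}

#' Metadata of a trace
#'
#' @param trace A `decat_trace` (or any object with a `metadata` attribute).
#' @return The metadata list (geometry, protocol, noise, labels, seed and,
#'   for simulated traces, the ground-truth schedule).
#' @export
trace_metadata <- function(trace) {
  attr(trace, "metadata")
}
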