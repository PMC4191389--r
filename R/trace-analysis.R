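# Measurement pipeline: smoothing, run/pause segmentation, conversion of
# elongations to released catenanes, and per-experiment kinetic features.
#
# Detection is two-stage. Candidate transition regions are flagged where
# the difference between adjacent multi-second window means exceeds a
# robust threshold; within each region, individual steps are localized by
# least-squares binary segmentation of the raw trace. Runs are then
# assembled by merging steps whose intervening plateau (as seen through the
# mandated 50-sample running average) is shorter than the pause resolution.

#' Centred running average
#'
#' Unweighted moving mean with the window centred on each sample; at the
#' edges the window shrinks to the available samples, so output length
#' equals input length. `window = 1` is the identity.
#'
#' @param x Numeric series.
#' @param window Window length in samples (`>= 1`, `<= length(x)`).
#' @return Numeric series of the same length.
#' @export
running_average <- function(x, window = 50) {
  n <- length(x)
  if (n == 0L) stop("Cannot smooth an empty series.", call. = FALSE)
  window <- as.integer(window)
  if (window < 1L || window > n) {
    stop("`window` must be between 1 and length(x).", call. = FALSE)
  }
  if (window == 1L) return(as.numeric(x))
  k1 <- (window - 1L) %/% 2L
  k2 <- window - 1L - k1
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - k1, 1L)
  hi <- pmin(i + k2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Difference between the means of the W samples after and before each
# point; zero within W of the edges.
block_mean_diff <- function(z, W) {
  n <- length(z)
  d <- numeric(n)
  if (n < 2L * W + 1L) return(d)
  cs <- cumsum(c(0, z))
  i <- seq(W, n - W)
  left <- (cs[i + 1L] - cs[i - W + 1L]) / W
  right <- (cs[i + W + 1L] - cs[i + 1L]) / W
  d[i] <- right - left
  d
}

# Contiguous TRUE stretches of a logical mask as (start, end) index pairs,
# expanded by `expand` samples and merged where they then overlap.
mask_regions <- function(mask, expand = 0L, n = length(mask)) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(matrix(integer(0), ncol = 2))
  s <- pmax(starts[keep] - expand, 1L)
  e <- pmin(ends[keep] + expand, n)
  # merge overlaps
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; out <- list()
  for (k in seq_along(s)[-1]) {
    if (s[k] <= me + 1L) me <- max(me, e[k]) else {
      out[[length(out) + 1L]] <- c(ms, me); ms <- s[k]; me <- e[k]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  do.call(rbind, out)
}

# Least-squares binary segmentation for mean shifts on y. Returns sorted
# breakpoints (index of the last sample of each left-hand segment).
# A split is accepted when the level difference reaches `min_step` and its
# Welch-type statistic reaches `t_min`.
binseg_steps <- function(y, sigma, min_step, t_min = 5, min_len = 5L) {
  n <- length(y)
  S <- cumsum(c(0, y))
  breaks <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    len <- j - i + 1L
    if (len < 2L * min_len) next
    k <- seq(i + min_len - 1L, j - min_len)
    n1 <- k - i + 1L
    n2 <- j - k
    m1 <- (S[k + 1L] - S[i]) / n1
    m2 <- (S[j + 1L] - S[k + 1L]) / n2
    tt <- abs(m2 - m1) / (sigma * sqrt(1 / n1 + 1 / n2))
    best <- which.max(tt)
    if (abs(m2[best] - m1[best]) >= min_step && tt[best] >= t_min) {
      kb <- k[best]
      breaks <- c(breaks, kb)
      stack[[length(stack) + 1L]] <- c(i, kb)
      stack[[length(stack) + 1L]] <- c(kb + 1L, j)
    }
  }
  sort(breaks)
}

#' Detect decatenation runs in a trace
#'
#' Segments an extension trace into braiding events and decatenation runs.
#' The trace is smoothed with the standard 50-sample running average;
#' candidate transitions are flagged by a paired-window mean difference
#' exceeding `threshold` robust standard deviations, individual release
#' steps are localized by binary segmentation of the raw samples, and steps
#' separated by plateaus shorter than `resolution` (plateaus as observable
#' after smoothing) are merged into a single run. Elongations are converted
#' to released catenanes through the braid geometry and rounded to
#' integers; candidates rounding to zero are discarded as noise.
#'
#' @param trace A `decat_trace` or a tibble with `time_s` and
#'   `extension_um` columns.
#' @param geom A [braid_geometry()]; defaults to the one in the trace
#'   metadata.
#' @param smooth_window Running-average window in samples.
#' @param resolution Shortest observable pause (s); plateaus shorter than
#'   this merge adjacent rises into one run.
#' @param threshold Detection threshold in robust standard deviations of
#'   the paired-window difference statistic.
#' @param detect_window Width of each paired window, in multiples of
#'   `smooth_window`.
#' @return A tibble of runs: `cycle`, `run`, `start_s` (first release),
#'   `end_s` (`start_s` + observed rise duration), `last_release_s`,
#'   `dz_um`, `delta_ca`, `rate_ca_s`. Attributes: `cycles` (per-cycle
#'   braid bookkeeping: completion time, post-braid level, estimated
#'   applied turns, relaxed level, full-decatenation time) and
#'   `params` (the thresholds used).
#' @export
detect_runs <- function(trace, geom = NULL, smooth_window = 50,
                        resolution = 1.0, threshold = 4.5,
                        detect_window = 3) {
  if (is.null(geom)) geom <- trace_metadata(trace)$geom
  if (is.null(geom)) {
    stop("No braid geometry: supply `geom` or a trace with metadata.",
         call. = FALSE)
  }
  stopifnot(inherits(geom, "braid_geometry"))
  times <- trace$time_s
  z <- trace$extension_um
  n <- length(z)
  if (n < 4L * smooth_window) {
    stop("Trace too short to segment.", call. = FALSE)
  }
  dt <- stats::median(diff(times))
  w <- as.integer(smooth_window)
  Wd <- as.integer(detect_window * w)

  if (max(z) > geom$l + max(5 * stats::mad(diff(z)), 0.2)) {
    stop("Observed extensions exceed the relaxed length of this geometry.",
         call. = FALSE)
  }

  s <- running_average(z, w)
  sigma_raw <- max(stats::mad(z - s), 1e-9)
  d <- block_mean_diff(z, Wd)
  # two-pass noise scale: events and ramps inflate a single global MAD when
  # the trace is event-dense, so re-estimate on the quiet baseline only
  sigma_d <- max(stats::mad(d), 1e-9)
  loud <- mask_regions(abs(d) > 3 * sigma_d, expand = Wd, n = n)
  if (nrow(loud) > 0) {
    qmask <- rep(TRUE, n)
    for (k in seq_len(nrow(loud))) qmask[loud[k, 1]:loud[k, 2]] <- FALSE
    if (sum(qmask) > 10L * Wd) {
      sigma_d <- max(stats::mad(d[qmask]), 1e-9)
    }
  }

  # falls fragment when |d| re-crosses the threshold near the ramp end;
  # expanding by one smoothing window re-merges the pieces
  fall <- mask_regions(d < -threshold * sigma_d, expand = w, n = n)
  rise <- mask_regions(d > threshold * sigma_d, expand = Wd, n = n)

  # ---- braiding events -> per-cycle bookkeeping -------------------------
  min_step <- 0.5 * geom$delta
  cycles <- NULL
  if (nrow(fall) > 0) {
    cyc_rows <- lapply(seq_len(nrow(fall)), function(k) {
      s0 <- fall[k, 1]; e0 <- fall[k, 2]
      post_idx <- seq(min(e0 + 1L, n), min(e0 + 2L * w, n))
      post_level <- stats::median(z[post_idx])
      pre_idx <- seq(max(s0 - 2L * w, 1L), max(s0 - 1L, 1L))
      pre_level <- stats::median(z[pre_idx])
      # level-crossing localization of the ramp end, bias-corrected for the
      # crossing threshold via the local ramp slope
      th_cross <- max(geom$delta / 4, 3 * sigma_raw / sqrt(w / 3))
      idx_win <- seq(s0, min(e0 + 2L * w, n))
      below <- idx_win[s[idx_win] <= post_level + th_cross]
      cross <- if (length(below)) below[1] else e0
      slope_idx <- max(cross - w, 1L)
      slope <- (s[slope_idx] - s[cross]) / ((cross - slope_idx) * dt)
      if (!is.finite(slope) || slope <= 0) {
        slope <- (pre_level - post_level) / max((e0 - s0) * dt, dt)
      }
      completion <- times[cross] + th_cross / slope
      tibble::tibble(
        completion_s = completion, post_level_um = post_level,
        pre_level_um = pre_level,
        applied_turns_est = round(ca_of_extension(geom, post_level))
      )
    })
    cycles <- dplyr::bind_rows(cyc_rows)
    cycles <- cycles[order(cycles$completion_s), ]
    cycles$cycle <- seq_len(nrow(cycles))
  } else {
    cycles <- tibble::tibble(
      completion_s = numeric(0), post_level_um = numeric(0),
      pre_level_um = numeric(0), applied_turns_est = numeric(0),
      cycle = integer(0)
    )
  }
  relaxed_level <- if (nrow(cycles) > 0) cycles$pre_level_um[1] else
    stats::median(z[seq_len(min(n, 4L * w))])
  cycles$relaxed_level_um <- rep(relaxed_level, nrow(cycles))

  # ---- release steps within rise regions --------------------------------
  steps <- NULL
  if (nrow(rise) > 0) {
    # keep rise regions clear of braiding ramps
    step_rows <- lapply(seq_len(nrow(rise)), function(k) {
      a <- rise[k, 1]; b <- rise[k, 2]
      if (nrow(fall) > 0) {
        # clip against any overlapping fall region
        for (f in seq_len(nrow(fall))) {
          if (fall[f, 1] <= b && fall[f, 2] >= a) {
            if (fall[f, 2] < (a + b) / 2) a <- max(a, fall[f, 2] + 1L)
            else b <- min(b, fall[f, 1] - 1L)
          }
        }
      }
      if (b - a + 1L < 10L) return(NULL)
      y <- z[a:b]
      br <- binseg_steps(y, sigma_raw, min_step = min_step)
      if (length(br) == 0L) return(NULL)
      bounds <- c(0L, br, length(y))
      levels <- vapply(seq_len(length(bounds) - 1L), function(q) {
        mean(y[(bounds[q] + 1L):bounds[q + 1L]])
      }, numeric(1))
      tibble::tibble(
        idx = a + br - 1L,
        time_s = times[a + br - 1L] + dt / 2,
        level_before = levels[-length(levels)],
        level_after = levels[-1],
        dz = diff(levels)
      )
    })
    steps <- dplyr::bind_rows(step_rows)
  }
  if (is.null(steps) || nrow(steps) == 0L) {
    runs <- empty_runs_tibble()
    attr(runs, "cycles") <- finalize_cycles(cycles, runs, geom)
    attr(runs, "params") <- list(smooth_window = w, resolution = resolution,
                                 threshold = threshold, dt = dt)
    return(runs)
  }
  steps <- steps[order(steps$time_s), ]
  # decatenation only elongates; downward jumps inside a rise region are
  # segmentation artefacts
  steps <- steps[steps$dz > 0, ]

  # Confirmation pass: a genuine release shifts the plateau level
  # persistently, while threshold excursions of the detection statistic do
  # not. Re-measure each candidate's level change with wide flanking
  # windows (robust medians, capped at neighbouring steps and braiding
  # regions) and discard candidates below half a turn.
  if (nrow(steps) > 0) {
    flank <- 10L * w
    ks <- steps$idx
    nst <- nrow(steps)
    lw <- steps$level_before
    rw <- steps$level_after
    for (q in seq_len(nst)) {
      k <- ks[q]
      lo <- max(k - flank, 1L, if (q > 1L) ks[q - 1L] + 1L else 1L)
      hi <- min(k + flank, n, if (q < nst) ks[q + 1L] else n)
      if (nrow(fall) > 0) {
        below <- fall[fall[, 2] < k & fall[, 2] >= lo, 2]
        if (length(below)) lo <- max(below) + 1L
        above <- fall[fall[, 1] > k & fall[, 1] <= hi, 1]
        if (length(above)) hi <- min(above) - 1L
      }
      if (k - lo + 1L >= w / 2) lw[q] <- stats::median(z[lo:k])
      if (hi - k >= w / 2) rw[q] <- stats::median(z[(k + 1L):hi])
    }
    steps$level_before <- lw
    steps$level_after <- rw
    steps <- steps[rw - lw >= 0.5 * geom$delta, , drop = FALSE]
  }

  runs <- empty_runs_tibble()
  if (nrow(steps) > 0) {
    # merge steps whose observable plateau (gap minus the smoothing rise
    # time) is shorter than the pause resolution
    gap_obs <- c(Inf, diff(steps$time_s)) - w * dt
    grp <- cumsum(gap_obs >= resolution)
    run_rows <- lapply(split(seq_len(nrow(steps)), grp), function(ii) {
      first <- ii[1]; last <- ii[length(ii)]
      onset <- steps$time_s[first]
      offset <- steps$time_s[last]
      lev_b <- steps$level_before[first]
      lev_a <- steps$level_after[last]
      dz <- lev_a - lev_b
      dca <- round(ca_of_extension(geom, lev_b) - ca_of_extension(geom, lev_a))
      duration <- (offset - onset) + w * dt
      tibble::tibble(
        start_s = onset, end_s = onset + duration, last_release_s = offset,
        dz_um = dz, delta_ca = dca, rate_ca_s = dca / duration
      )
    })
    runs <- dplyr::bind_rows(run_rows)
    runs <- runs[runs$delta_ca >= 1, , drop = FALSE]
  }
  if (nrow(runs) > 0) {
    runs$cycle <- if (nrow(cycles) > 0) {
      findInterval(runs$start_s, cycles$completion_s)
    } else 1L
    runs <- runs[runs$cycle >= 1L, , drop = FALSE]
    runs <- runs[order(runs$start_s), ]
    runs$run <- stats::ave(runs$start_s, runs$cycle, FUN = seq_along)
    runs <- runs[, c("cycle", "run", "start_s", "end_s", "last_release_s",
                     "dz_um", "delta_ca", "rate_ca_s")]
    # recover the final plateau level of each run for decatenation tracking
    runs$level_after_um <- vapply(runs$last_release_s, function(tt) {
      i <- findInterval(tt, steps$time_s)
      steps$level_after[i]
    }, numeric(1))
  }
  attr(runs, "cycles") <- finalize_cycles(cycles, runs, geom)
  attr(runs, "params") <- list(smooth_window = w, resolution = resolution,
                               threshold = threshold, dt = dt)
  runs
}

empty_runs_tibble <- function() {
  tibble::tibble(
    cycle = integer(0), run = integer(0), start_s = numeric(0),
    end_s = numeric(0), last_release_s = numeric(0), dz_um = numeric(0),
    delta_ca = numeric(0), rate_ca_s = numeric(0),
    level_after_um = numeric(0)
  )
}

# Attach per-cycle full-decatenation times: a cycle is fully decatenated
# when the level after its last run returns to within half a turn of the
# relaxed extension.
finalize_cycles <- function(cycles, runs, geom) {
  if (nrow(cycles) == 0L) return(cycles)
  cycles$full_decat_s <- NA_real_
  cycles$n_released <- 0
  if (nrow(runs) > 0) {
    for (c in cycles$cycle) {
      rr <- runs[runs$cycle == c, ]
      if (nrow(rr) == 0L) next
      cycles$n_released[cycles$cycle == c] <- sum(rr$delta_ca)
      last <- rr[nrow(rr), ]
      if (abs(last$level_after_um - cycles$relaxed_level_um[1]) <=
          geom$delta / 2) {
        cycles$full_decat_s[cycles$cycle == c] <- last$last_release_s
      }
    }
  }
  cycles
}

#' Extract the five kinetic features of an experiment
#'
#' Converts a detected run table into the per-experiment kinetic features:
#' initial time lag (braid completion to first run, one per braiding
#' cycle), secondary time lags (last release of a run to the start of the
#' next), run sizes, per-run rates, and — for cycles that reach full
#' decatenation — the total decatenation rate (catenanes released divided
#' by the time from braid completion to full decatenation). Each re-braid
#' starts a new initial lag; only within-cycle gaps count as secondary.
#'
#' @param runs A run tibble from [detect_runs()].
#' @param cycles Per-cycle bookkeeping; defaults to `attr(runs, "cycles")`.
#' @param applied_turns Optional known applied turns per cycle (scalar or
#'   vector); when given, a cycle's total rate is reported only if the
#'   detected releases account for all applied turns.
#' @return A long tibble with columns `cycle`, `feature`
#'   (`"initial_lag"`, `"secondary_lag"`, `"run_size"`, `"run_rate"`,
#'   `"total_rate"`) and `value`.
#' @export
extract_summary <- function(runs, cycles = attr(runs, "cycles"),
                            applied_turns = NULL) {
  if (is.null(cycles) || nrow(cycles) == 0L) {
    stop("No braiding-cycle bookkeeping: run detect_runs() first or supply `cycles`.",
         call. = FALSE)
  }
  if (nrow(runs) > 1L) {
    by_cycle <- split(runs, runs$cycle)
    for (rr in by_cycle) {
      if (nrow(rr) > 1L &&
          any(diff(rr$start_s) <= 0 |
              rr$last_release_s[-nrow(rr)] > rr$start_s[-1])) {
        stop("Runs overlap or are out of order within a cycle.", call. = FALSE)
      }
    }
  }
  if (!is.null(applied_turns)) {
    applied_turns <- rep_len(applied_turns, nrow(cycles))
  }
  out <- list()
  for (k in seq_len(nrow(cycles))) {
    cy <- cycles[k, ]
    rr <- runs[runs$cycle == cy$cycle, , drop = FALSE]
    if (nrow(rr) == 0L) next
    feats <- list(
      tibble::tibble(cycle = cy$cycle, feature = "initial_lag",
                     value = max(rr$start_s[1] - cy$completion_s, 0)),
      tibble::tibble(cycle = cy$cycle, feature = "run_size",
                     value = as.numeric(rr$delta_ca)),
      tibble::tibble(cycle = cy$cycle, feature = "run_rate",
                     value = rr$rate_ca_s)
    )
    if (nrow(rr) > 1L) {
      feats <- c(feats, list(tibble::tibble(
        cycle = cy$cycle, feature = "secondary_lag",
        value = rr$start_s[-1] - rr$last_release_s[-nrow(rr)]
      )))
    }
    if (!is.na(cy$full_decat_s)) {
      total <- sum(rr$delta_ca)
      ok <- is.null(applied_turns) || total == applied_turns[k]
      if (ok) {
        feats <- c(feats, list(tibble::tibble(
          cycle = cy$cycle, feature = "total_rate",
          value = total / (cy$full_decat_s - cy$completion_s)
        )))
      }
    }
    out[[length(out) + 1L]] <- dplyr::bind_rows(feats)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(cycle = integer(0), feature = character(0),
                          value = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Braid quality control
#'
#' Accepts or rejects a candidate braid from its extension-versus-rotation
#' curves: a usable braid shows a nearly left-right symmetric curve at
#' every force (a supercoiling tether produces an asymmetric one) and its
#' two tethers have matching relaxed extensions.
#'
#' @param curves Tibble with columns `ca`, `extension_um` and optionally
#'   `force_pn`; each force's `ca` grid must be symmetric about zero and
#'   include zero.
#' @param relaxed_extensions Numeric vector of length 2: the relaxed
#'   extensions of the two tethers (micrometres).
#' @param sym_tol Maximum allowed `max |z(Ca) - z(-Ca)| / l`.
#' @param ext_tol Maximum allowed difference between the relaxed
#'   extensions (micrometres).
#' @return An object of class `braid_qc`: list with `accept` (logical),
#'   `symmetry` (tibble of per-force scores), `extension_diff_um`, and
#'   `flags` (character vector naming failed checks).
#' @export
qc_select_braid <- function(curves, relaxed_extensions, sym_tol = 0.05,
                            ext_tol = 0.1) {
  stopifnot(all(c("ca", "extension_um") %in% names(curves)))
  if (length(relaxed_extensions) != 2L) {
    stop("`relaxed_extensions` must give the two tethers' relaxed lengths.",
         call. = FALSE)
  }
  if (!("force_pn" %in% names(curves))) curves$force_pn <- NA_real_
  sym <- curves |>
    dplyr::group_by(.data$force_pn) |>
    dplyr::group_modify(function(df, key) {
      ca <- df$ca
      if (!all(sort(ca) == sort(-ca)) || !any(ca == 0)) {
        stop("Ca grid must be symmetric about zero and include zero.",
             call. = FALSE)
      }
      pos <- df[df$ca >= 0, ]
      neg <- df[df$ca <= 0, ]
      neg <- neg[match(-pos$ca, neg$ca), ]
      l0 <- df$extension_um[df$ca == 0][1]
      tibble::tibble(
        symmetry_score = max(abs(pos$extension_um - neg$extension_um)) / l0
      )
    }) |>
    dplyr::ungroup()
  ext_diff <- abs(diff(relaxed_extensions))
  flags <- character(0)
  if (any(sym$symmetry_score > sym_tol)) flags <- c(flags, "asymmetric_curve")
  if (ext_diff > ext_tol) flags <- c(flags, "relaxed_extension_mismatch")
  structure(
    list(accept = length(flags) == 0L, symmetry = sym,
         extension_diff_um = ext_diff, flags = flags,
         sym_tol = sym_tol, ext_tol = ext_tol),
    class = "braid_qc"
  )
}

#' @export
print.braid_qc <- function(x, ...) {
  cat(sprintf("<braid_qc> %s (max symmetry score %.3f, relaxed-extension diff %.3f um)\n",
              if (x$accept) "ACCEPT" else paste("REJECT:", paste(x$flags, collapse = ", ")),
              max(x$symmetry$symmetry_score), x$extension_diff_um))
  invisible(x)
}
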