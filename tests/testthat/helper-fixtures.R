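# Fixtures built in code: reference geometries, hand-made staircase traces
# and brute-force oracles used across the test files.

test_geom <- function() braid_geometry(l = 2.3, beta = 47, ca_max = 50)

# A trace that is flat except for instantaneous upward steps of
# `sizes` turns at `step_times`; starts at catenation `ca0`.
staircase_trace <- function(geom, ca0, step_times, sizes = 1,
                            duration = max(step_times) + 60,
                            sample_rate = 50, sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep_len(sizes, length(step_times))
  t <- seq(0, duration, by = 1 / sample_rate)
  ca <- ca0 - colSums(outer(step_times, t, function(st, tt) tt >= st) * sizes)
  z <- braid_extension(geom, ca)
  if (sigma > 0) z <- z + rnorm(length(z), sd = sigma)
  tibble::tibble(time_s = t, extension_um = z)
}

# A trace with a braiding ramp (so cycle bookkeeping exists) followed by
# steps: relaxed hold, linear ramp down to `turns`, then the staircase.
braided_staircase_trace <- function(geom, turns, step_times, sizes = 1,
                                    lead_in = 10, ramp = 30,
                                    duration = max(step_times) + 60,
                                    sample_rate = 50, sigma = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep_len(sizes, length(step_times))
  t <- seq(0, duration, by = 1 / sample_rate)
  ca <- ifelse(t < lead_in, 0,
        ifelse(t < lead_in + ramp, (t - lead_in) / ramp * turns, turns))
  rel <- colSums(outer(step_times, t, function(st, tt) tt >= st) * sizes)
  ca <- pmax(ca - rel, 0)
  z <- braid_extension(geom, ca)
  if (sigma > 0) z <- z + rnorm(length(z), sd = sigma)
  tibble::tibble(time_s = t, extension_um = z)
}

# Brute-force pooled-variance two-sided t test (textbook formula), the
# independent oracle for compare_groups().
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t), df = n1 + n2 - 2)
  list(statistic = t, p.value = p)
}

# Exhaustive two-group split over *all* 2-partitions (not only interval
# splits): oracle for the 1-D two-means step of the angle classifier.
oracle_best_partition <- function(x) {
  n <- length(x)
  best <- NULL; best_ss <- Inf
  for (m in 1:(n - 1)) {
    combos <- utils::combn(n, m)
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      a <- x[idx]; b <- x[-idx]
      ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
      if (ss < best_ss - 1e-12) {
        best_ss <- ss
        best <- sort(a)
        if (mean(a) > mean(b)) best <- sort(b)
      }
    }
  }
  list(small = best, ss = best_ss)
}

# An asymmetric "hat" curve like a single supercoiled tether: linear
# shortening for positive turns, a flat plateau for negative ones.
supercoil_hat_curve <- function(l = 2.3, slope = 0.04, ca_max = 15) {
  ca <- seq(-ca_max, ca_max)
  z <- ifelse(ca >= 0, l - slope * ca, l - 0.002 * abs(ca))
  tibble::tibble(ca = ca, extension_um = z, force_pn = 2.0)
}
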