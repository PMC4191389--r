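# Cohort statistics: dwell-time histogram fitting, group comparison and
# crossover-angle classification.

#' Fit an exponential decay to a dwell-time histogram
#'
#' Bins the values from zero and fits `A * exp(-t / t1)` to the bin counts
#' at the bin centres by weighted least squares, with Poisson square-root
#' counting errors as weights — the histogram-fit procedure customarily
#' applied to single-molecule dwell-time distributions. The reported `t1`
#' is the mean waiting time. Maximum likelihood (for which the exponential
#' mean estimate is simply the sample mean) is available as an alternative
#' estimator and as a cross-check.
#'
#' @param values Non-negative dwell times (at least 10).
#' @param bin_width Histogram bin width in the unit of `values`; default
#'   `max(values) / 8`, giving at least 8 bins.
#' @param method `"wls"` (weighted least squares on the histogram, the
#'   default) or `"mle"` (sample mean).
#' @param min_n Minimum number of values required.
#' @return An object of class `exp_fit` with fields `t1`, `t1_se`,
#'   `amplitude`, `n`, `bin_width`, `method` and `histogram` (tibble of
#'   `mid`, `count`). Use [generics::tidy()] / [generics::glance()] to get
#'   tibble summaries.
#' @examples
#' fit <- fit_exponential_histogram(rexp(2000, 1 / 13), bin_width = 4)
#' glance(fit)
#' @export
fit_exponential_histogram <- function(values, bin_width = NULL,
                                      method = c("wls", "mle"),
                                      min_n = 10) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (any(values < 0)) stop("Dwell times must be non-negative.", call. = FALSE)
  n <- length(values)
  if (n < min_n) {
    stop(sprintf("Need at least %d values to fit (got %d).", min_n, n),
         call. = FALSE)
  }
  vmax <- max(values)
  if (vmax <= 0) stop("Degenerate histogram: all values are zero.", call. = FALSE)
  if (is.null(bin_width)) bin_width <- vmax / 8
  if (bin_width <= 0) stop("`bin_width` must be positive.", call. = FALSE)
  breaks <- seq(0, vmax + bin_width, by = bin_width)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  mids <- breaks[-1] - bin_width / 2
  keep <- counts > 0
  if (sum(keep) < 3L) {
    stop("Fewer than 3 non-empty bins: histogram is degenerate.", call. = FALSE)
  }
  hist_tbl <- tibble::tibble(mid = mids, count = counts)

  if (method == "mle") {
    t1 <- mean(values)
    return(new_exp_fit(t1 = t1, t1_se = t1 / sqrt(n), amplitude = NA_real_,
                       n = n, bin_width = bin_width, method = method,
                       histogram = hist_tbl))
  }

  df <- data.frame(x = mids[keep], y = counts[keep])
  # log-linear start values
  lmfit <- stats::lm(log(y) ~ x, data = df, weights = df$y)
  t1_0 <- unname(-1 / stats::coef(lmfit)[2])
  if (!is.finite(t1_0) || t1_0 <= 0) t1_0 <- mean(values)
  A0 <- unname(exp(stats::coef(lmfit)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x / t1), data = df,
                      start = list(A = A0, t1 = t1_0),
                      weights = 1 / df$y,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf("Exponential histogram fit failed to converge: %s",
                   conditionMessage(e)), call. = FALSE)
    }
  )
  co <- summary(fit)$coefficients
  if (co["t1", "Estimate"] <= 0) {
    stop("Exponential histogram fit converged to a non-positive mean.",
         call. = FALSE)
  }
  new_exp_fit(
    t1 = co["t1", "Estimate"], t1_se = co["t1", "Std. Error"],
    amplitude = co["A", "Estimate"], n = n, bin_width = bin_width,
    method = method, histogram = hist_tbl
  )
}

new_exp_fit <- function(t1, t1_se, amplitude, n, bin_width, method,
                        histogram) {
  structure(
    list(t1 = t1, t1_se = t1_se, amplitude = amplitude, n = n,
         bin_width = bin_width, method = method, histogram = histogram),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> t1 = %.3g +/- %.2g (n = %d, bin width %.3g, %s)\n",
              x$t1, x$t1_se, x$n, x$bin_width, x$method))
  invisible(x)
}

#' @rdname fit_exponential_histogram
#' @param x An `exp_fit` object.
#' @param ... Unused.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("t1", "amplitude"),
    estimate = c(x$t1, x$amplitude),
    std.error = c(x$t1_se, NA_real_)
  )
}

#' @rdname fit_exponential_histogram
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(t1 = x$t1, t1_se = x$t1_se, amplitude = x$amplitude,
                 n = x$n, bin_width = x$bin_width, method = x$method)
}

#' Arithmetic mean with standard error
#'
#' @param values Numeric vector, non-empty.
#' @return One-row tibble with `mean`, `se` (`NA` for a single value) and
#'   `n`.
#' @export
arithmetic_mean_se <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("Cannot average an empty vector.", call. = FALSE)
  se <- if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_
  tibble::tibble(mean = mean(values), se = se, n = n)
}

#' Two-sample Student's t test
#'
#' Pooled-variance, two-sided two-sample t test for a difference in means
#' between two groups of dwell times or rates. When both groups are
#' constant, the statistic is 0 and P = 1 if the means agree, and the
#' difference is reported as infinitely significant otherwise.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return One-row tibble: `statistic` (t, computed as mean(a) - mean(b)
#'   over its pooled standard error), `p.value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("Both groups need at least 2 values.", call. = FALSE)
  }
  df <- length(a) + length(b) - 2
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(statistic = 0, p.value = 1, df = df,
                            mean_a = mean(a), mean_b = mean(b)))
    }
    return(tibble::tibble(statistic = sign(mean(a) - mean(b)) * Inf,
                          p.value = 0, df = df,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), p.value = tt$p.value,
                 df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Fraction of exponential events occurring within a time
#'
#' For an exponential waiting-time distribution with mean `t1`, the
#' fraction of events that have occurred by time `t`: `1 - exp(-t / t1)`.
#'
#' @param t1 Mean waiting time (positive).
#' @param t Elapsed time (non-negative).
#' @return Fraction in `[0, 1]`.
#' @examples
#' exponential_fraction_within(13, 29) # ~0.89, i.e. ~90% of events
#' @export
exponential_fraction_within <- function(t1, t) {
  if (any(t1 <= 0)) stop("`t1` must be positive.", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative.", call. = FALSE)
  1 - exp(-t / t1)
}

#' Classify crossover angles into two groups
#'
#' Splits a set of measured crossover angles into a small-angle and a
#' large-angle group at the split of the sorted values minimizing the
#' within-group sum of squares (the exact 1-D two-means solution), then
#' iteratively discards angles farther than `max_dev` from the mean of the
#' rest of their group — re-splitting the retained angles — until stable.
#'
#' @param angles Crossover angles in degrees (at least 2).
#' @param max_dev Maximum allowed distance from the group mean (degrees).
#' @return An object of class `angle_classes`: list with `small`, `large`
#'   (numeric vectors), `small_mean`, `large_mean`, `discarded`, and
#'   `degenerate` (TRUE when all angles collapse into one group).
#' @export
classify_crossover_angles <- function(angles, max_dev = 10) {
  angles <- angles[is.finite(angles)]
  if (length(angles) < 2L) {
    stop("Need at least 2 angles to classify.", call. = FALSE)
  }
  retained <- sort(angles)
  discarded <- numeric(0)
  repeat {
    if (length(unique(retained)) == 1L) {
      return(structure(
        list(small = retained, large = numeric(0),
             small_mean = mean(retained), large_mean = NA_real_,
             discarded = discarded, degenerate = TRUE),
        class = "angle_classes"
      ))
    }
    sp <- best_two_split(retained)
    small <- retained[seq_len(sp)]
    large <- retained[-seq_len(sp)]
    # deviation of each angle from the mean of the rest of its group, so a
    # single outlier cannot mask itself by dragging the mean along
    dev_small <- loo_deviation(small)
    dev_large <- loo_deviation(large)
    worst <- max(c(dev_small, dev_large))
    if (worst <= max_dev) {
      return(structure(
        list(small = small, large = large,
             small_mean = mean(small), large_mean = mean(large),
             discarded = discarded, degenerate = FALSE),
        class = "angle_classes"
      ))
    }
    bad <- c(small[which(dev_small == worst)], large[which(dev_large == worst)])[1]
    discarded <- c(discarded, bad)
    retained <- retained[-match(bad, retained)]
    if (length(retained) < 2L) {
      return(structure(
        list(small = retained, large = numeric(0),
             small_mean = mean(retained), large_mean = NA_real_,
             discarded = discarded, degenerate = TRUE),
        class = "angle_classes"
      ))
    }
  }
}

# |x_i - mean(x[-i])|; zero for a singleton group.
loo_deviation <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  abs(x - (sum(x) - x) / (n - 1L))
}

# Index of the last element of the lower group in the optimal two-interval
# split of sorted x (minimum within-group sum of squares; ties go to the
# split with smaller total within-group variance, i.e. the first optimum).
best_two_split <- function(x) {
  n <- length(x)
  ss <- vapply(seq_len(n - 1L), function(k) {
    a <- x[seq_len(k)]; b <- x[-seq_len(k)]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  which.min(ss)
}

#' @export
print.angle_classes <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<angle_classes> degenerate: one group at %.1f deg (n = %d), %d discarded\n",
                x$small_mean, length(x$small), length(x$discarded)))
  } else {
    cat(sprintf("<angle_classes> small %.1f deg (n = %d), large %.1f deg (n = %d), %d discarded\n",
                x$small_mean, length(x$small), x$large_mean, length(x$large),
                length(x$discarded)))
  }
  invisible(x)
}

#' @rdname classify_crossover_angles
#' @param x An `angle_classes` object.
#' @param ... Unused.
#' @export
tidy.angle_classes <- function(x, ...) {
  tibble::tibble(
    angle = c(x$small, x$large, x$discarded),
    group = c(rep("small", length(x$small)), rep("large", length(x$large)),
              rep("discarded", length(x$discarded)))
  )
}

#' @rdname classify_crossover_angles
#' @export
glance.angle_classes <- function(x, ...) {
  tibble::tibble(small_mean = x$small_mean, large_mean = x$large_mean,
                 n_small = length(x$small), n_large = length(x$large),
                 n_discarded = length(x$discarded), degenerate = x$degenerate)
}

#' Summarize a cohort of experiments
#'
#' Aggregates per-experiment kinetic features into a report shaped like the
#' customary per-enzyme (or per-angle-class) parameter table. Time lags are
#' estimated by the exponential histogram fit ([fit_exponential_histogram()]);
#' run sizes, per-run rates and total rates by the arithmetic mean with its
#' standard error. (An exponential decay is only a meaningful model for
#' monotonically decaying dwell-time histograms; the simulated rate
#' distributions are sharply peaked, so rates are averaged.) If a lag fit
#' fails or has too few values, the arithmetic estimator is used and
#' flagged.
#'
#' @param features Long feature tibble (columns `feature`, `value`, plus
#'   any grouping columns such as `enzyme`, `substrate`, `angle_class`),
#'   e.g. rows of [extract_summary()] bound across experiments.
#' @param group_by Character vector of grouping column names (default: the
#'   intersection of `c("enzyme", "substrate", "angle_class")` with the
#'   columns present).
#' @param min_fit_n Minimum number of values for the exponential fit.
#' @param warn_n Emit a warning for cells with fewer values than this.
#' @return A tibble with one row per group x feature: grouping columns,
#'   `feature`, `estimate`, `error`, `n`, `estimator`.
#' @export
summarize_cohort <- function(features, group_by = NULL, min_fit_n = 10,
                             warn_n = 10) {
  stopifnot(all(c("feature", "value") %in% names(features)))
  if (is.null(group_by)) {
    group_by <- intersect(c("enzyme", "substrate", "angle_class"),
                          names(features))
  }
  lag_features <- c("initial_lag", "secondary_lag")
  features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "feature")))) |>
    dplyr::group_modify(function(df, key) {
      v <- df$value[is.finite(df$value)]
      if (length(v) == 0L) {
        warning(sprintf("Empty cell for feature '%s'; omitted.", key$feature))
        return(tibble::tibble(estimate = NA_real_, error = NA_real_,
                              n = 0L, estimator = "none"))
      }
      if (length(v) < warn_n) {
        warning(sprintf("Only %d values for feature '%s'.",
                        length(v), key$feature))
      }
      if (key$feature %in% lag_features && length(v) >= min_fit_n) {
        fit <- tryCatch(fit_exponential_histogram(v), error = function(e) NULL)
        if (!is.null(fit)) {
          return(tibble::tibble(estimate = fit$t1, error = fit$t1_se,
                                n = fit$n, estimator = "exponential_fit"))
        }
      }
      m <- arithmetic_mean_se(v)
      tibble::tibble(estimate = m$mean, error = m$se, n = m$n,
                     estimator = "arithmetic")
    }) |>
    dplyr::ungroup()
}
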