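# ggplot2 visualisations of traces, fits and geometry.

#' Plot a decatenation trace
#'
#' Raw extension in grey with the 50-sample running average overlaid, the
#' standard way braid decatenation traces are displayed; detected runs can
#' be shaded by passing the result of [detect_runs()].
#'
#' @param object A `decat_trace`.
#' @param runs Optional run tibble from [detect_runs()].
#' @param smooth_window Running-average window (samples).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decat_trace <- function(object, runs = NULL, smooth_window = 50,
                                 ...) {
  df <- tibble::tibble(
    time_s = object$time_s,
    raw = object$extension_um,
    smooth = running_average(object$extension_um, smooth_window)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$raw), colour = "grey70",
                       linewidth = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "firebrick",
                       linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "extension (µm)")
  if (!is.null(runs) && nrow(runs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = runs,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  p
}

#' Plot an exponential histogram fit
#'
#' @param object An `exp_fit` from [fit_exponential_histogram()].
#' @param ... Unused.
#' @return A ggplot object: the dwell-time histogram with square-root
#'   counting error bars and the fitted decay curve.
#' @export
autoplot.exp_fit <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width * 0.9, fill = "grey80",
                      colour = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$count - sqrt(.data$count), 0),
                   ymax = .data$count + sqrt(.data$count)),
      width = object$bin_width * 0.3
    ) +
    ggplot2::labs(x = "value", y = "count")
  if (is.finite(object$amplitude)) {
    grid <- tibble::tibble(
      mid = seq(0, max(h$mid), length.out = 200),
      count = object$amplitude * exp(-seq(0, max(h$mid), length.out = 200) /
                                       object$t1)
    )
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot the extension-versus-catenation curve of a geometry
#'
#' @param geom A [braid_geometry()].
#' @param ca_range Maximum |Ca| plotted.
#' @return A ggplot object showing the symmetric braid curve with its
#'   sharp peak at zero turns.
#' @export
plot_braid_curve <- function(geom, ca_range = min(geom$ca_max, 35)) {
  df <- braid_curve(geom, ca_range = ca_range, step = 0.25)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ca, y = .data$extension_um)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$ca %% 1 == 0, ], size = 0.8) +
    ggplot2::labs(x = "catenation number Ca (turns)",
                  y = "extension (µm)")
}
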