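# File formats: tab-separated traces with a JSON metadata sidecar.

meta_path_for <- function(path) paste0(path, ".meta.json")

#' Write a trace to disk
#'
#' Writes the extension time series as two-column tab-separated text with
#' header `time_s<TAB>extension_um`, and the metadata (geometry, protocol,
#' noise model, labels, seed and — for simulated traces — the ground-truth
#' schedule) as a JSON sidecar at `<path>.meta.json`.
#'
#' @param trace A `decat_trace` or tibble with `time_s`, `extension_um`.
#' @param path Output file path (conventionally `.tsv`).
#' @param digits Significant digits written (default 12; round-trips to
#'   well below a nanometre).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, digits = 12) {
  df <- data.frame(time_s = signif(trace$time_s, digits),
                   extension_um = signif(trace$extension_um, digits))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- trace_metadata(trace)
  if (!is.null(meta)) {
    jsonlite::write_json(serialize_metadata(meta), meta_path_for(path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

serialize_metadata <- function(meta) {
  out <- list(
    geometry = list(l_um = meta$geom$l, h_um = meta$geom$h,
                    beta_deg = meta$geom$beta,
                    delta_um_per_turn = meta$geom$delta,
                    ca_max = meta$geom$ca_max),
    protocol = unclass(meta$protocol),
    noise = unclass(meta$noise),
    enzyme = meta$enzyme, substrate = meta$substrate,
    angle_class = meta$angle_class, seed = meta$seed,
    package_version = as.character(utils::packageVersion("decatr"))
  )
  if (!is.null(meta$schedule)) {
    sched <- meta$schedule
    out$schedule <- list(
      active = sched$active,
      catalytic_cycles = sched$catalytic_cycles,
      cycles = as.data.frame(sched$cycles),
      events = as.data.frame(sched$events)
    )
  }
  out
}

deserialize_metadata <- function(js) {
  geom <- braid_geometry(l = js$geometry$l_um, h = js$geometry$h_um,
                         delta = js$geometry$delta_um_per_turn,
                         ca_max = js$geometry$ca_max)
  protocol <- do.call(decat_protocol, js$protocol[
    intersect(names(js$protocol), names(formals(decat_protocol)))])
  noise <- noise_model(sigma_z = js$noise$sigma_z,
                       corr_time = js$noise$corr_time)
  meta <- list(geom = geom, protocol = protocol, noise = noise,
               enzyme = js$enzyme, substrate = js$substrate,
               angle_class = js$angle_class, seed = js$seed)
  if (!is.null(js$schedule)) {
    meta$schedule <- structure(
      list(cycles = tibble::as_tibble(js$schedule$cycles),
           events = tibble::as_tibble(js$schedule$events),
           active = js$schedule$active,
           catalytic_cycles = js$schedule$catalytic_cycles,
           protocol = protocol, substrate = js$substrate),
      class = "event_schedule"
    )
    if (nrow(meta$schedule$events) == 0L) {
      meta$schedule$events <- tibble::tibble(cycle = integer(0),
                                             run = integer(0),
                                             time_s = numeric(0))
    }
  }
  meta
}

#' Read a trace from disk
#'
#' Reads a tab-separated trace written by [write_trace()] (or any
#' two-column numeric file with a `time_s`/`extension_um` header) and its
#' JSON metadata sidecar if present. Malformed rows are reported with their
#' line numbers; a non-uniform time grid (beyond 1% jitter) is a format
#' error.
#'
#' @param path Trace file path.
#' @param require_metadata Error if the sidecar is missing (analysis needs
#'   the braid geometry).
#' @return A `decat_trace` tibble.
#' @export
read_trace <- function(path, require_metadata = FALSE) {
  if (!file.exists(path)) stop(sprintf("No such trace file: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("time_s", "extension_um") %in% names(df))) {
    stop("Trace file must have columns `time_s` and `extension_um`.",
         call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(df$time_s))
  zm <- suppressWarnings(as.numeric(df$extension_um))
  bad <- which(!is.finite(tm) | !is.finite(zm))
  if (length(bad)) {
    stop(sprintf("Non-numeric trace rows at line(s): %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  dgrid <- diff(tm)
  if (length(dgrid) > 0) {
    dt <- stats::median(dgrid)
    if (any(dgrid <= 0) || any(abs(dgrid - dt) > 0.01 * dt)) {
      stop("Time grid is not uniform (more than 1% jitter).", call. = FALSE)
    }
  }
  out <- tibble::tibble(time_s = tm, extension_um = zm)
  mp <- meta_path_for(path)
  if (file.exists(mp)) {
    js <- jsonlite::read_json(mp, simplifyVector = TRUE)
    attr(out, "metadata") <- deserialize_metadata(js)
  } else if (require_metadata) {
    stop(sprintf(
      "No metadata sidecar at %s: supply the braid geometry to analyze this trace.",
      mp), call. = FALSE)
  }
  class(out) <- c("decat_trace", class(out))
  out
}

#' Write an experiment bundle
#'
#' @param trace A `decat_trace`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the bundle files.
#' @return Path of the trace file, invisibly.
#' @export
write_bundle <- function(trace, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trace(trace, file.path(dir, paste0(name, ".tsv")))
}
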