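# End-to-end harness: simulate a cohort, run the measurement pipeline on
# every trace, pool the kinetic features.

#' Simulate and analyze a cohort of experiments
#'
#' The round-trip used for validation and for campaign-level statistics:
#' for each experiment, draw an event schedule, render the noisy trace,
#' segment it with [detect_runs()] and extract features with
#' [extract_summary()]. Traces are processed one at a time and discarded,
#' so large campaigns stay within desk-scale memory.
#'
#' @inheritParams simulate_campaign
#' @param keep_traces Keep the rendered traces in the result (memory-heavy
#'   for long campaigns).
#' @param applied_turns_known Use the simulated applied turns when deciding
#'   whether a cycle's total rate is reportable (default TRUE; with FALSE
#'   the decision rests on the detected level returning to the relaxed
#'   extension alone).
#' @return An object of class `decat_campaign`: list with
#'   * `features`: long tibble (`experiment`, `cycle`, `feature`, `value`,
#'     plus `enzyme`, `substrate`, `angle_class`),
#'   * `runs`: all detected runs with an `experiment` column,
#'   * `experiments`: per-experiment overview (`experiment`, `seed`,
#'     `active_truth`, `n_runs_detected`, `n_released_truth`),
#'   * `config`: the condition that generated the cohort,
#'   * `traces`: list of traces if `keep_traces`.
#' @export
run_campaign <- function(n_experiments, params = NULL, geom = NULL,
                         protocol = decat_protocol(), noise = noise_model(),
                         enzyme = "topoIII", substrate = "bulge",
                         angle_class = "mixed", seed = 1,
                         keep_traces = FALSE, applied_turns_known = TRUE) {
  stopifnot(n_experiments >= 1)
  if (is.null(params) || is.null(geom)) {
    preset <- preset_condition(enzyme, substrate, angle_class)
    if (is.null(params)) params <- preset$params
    if (is.null(geom)) geom <- preset$geom
  }
  feats <- vector("list", n_experiments)
  runs_all <- vector("list", n_experiments)
  overview <- vector("list", n_experiments)
  traces <- if (keep_traces) vector("list", n_experiments) else NULL
  for (i in seq_len(n_experiments)) {
    tr <- simulate_experiment(params, geom, protocol, noise, enzyme,
                              substrate, angle_class,
                              seed = derive_seed(seed, i))
    sched <- trace_metadata(tr)$schedule
    runs <- detect_runs(tr, geom)
    applied <- if (applied_turns_known) sched$cycles$turns else NULL
    fe <- extract_summary(runs, applied_turns = applied)
    if (nrow(fe) > 0) fe$experiment <- i
    if (nrow(runs) > 0) runs$experiment <- i
    feats[[i]] <- fe
    runs_all[[i]] <- runs
    overview[[i]] <- tibble::tibble(
      experiment = i, seed = derive_seed(seed, i),
      active_truth = sched$active,
      n_runs_detected = nrow(runs),
      n_released_truth = nrow(sched$events)
    )
    if (keep_traces) traces[[i]] <- tr
  }
  features <- dplyr::bind_rows(feats)
  if (nrow(features) > 0) {
    features$enzyme <- enzyme
    features$substrate <- substrate
    features$angle_class <- angle_class
  }
  structure(
    list(features = features, runs = dplyr::bind_rows(runs_all),
         experiments = dplyr::bind_rows(overview),
         config = list(params = params, geom = geom, protocol = protocol,
                       noise = noise, enzyme = enzyme, substrate = substrate,
                       angle_class = angle_class, seed = seed,
                       n_experiments = n_experiments),
         traces = traces),
    class = "decat_campaign"
  )
}

#' @export
print.decat_campaign <- function(x, ...) {
  cat(sprintf(
    "<decat_campaign> %d experiments (%s, %s, %s angle): %d runs detected, %d/%d active\n",
    x$config$n_experiments, x$config$enzyme, x$config$substrate,
    x$config$angle_class, nrow(x$runs),
    sum(x$experiments$n_runs_detected > 0), nrow(x$experiments)
  ))
  invisible(x)
}

#' Cohort summary table for a campaign
#'
#' @param campaign A [run_campaign()] result.
#' @param ... Passed to [summarize_cohort()].
#' @return The [summarize_cohort()] tibble for the campaign's features.
#' @export
campaign_summary <- function(campaign, ...) {
  stopifnot(inherits(campaign, "decat_campaign"))
  summarize_cohort(campaign$features, ...)
}
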