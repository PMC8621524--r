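#' Default run configuration
#'
#' A run configuration bundles named model-parameter overrides, protocol
#' schedule fields, analysis thresholds, and output options.  It is the
#' single object the command-line interface and [run_experiment()]
#' consume; [read_run_config()] loads one from YAML, and every run writes
#' a fully resolved copy next to its outputs so results are reproducible
#' from the echo alone.
#'
#' @return A nested list of class `run_config` with elements `parameters`
#'   (overrides for [model_parameters()]), `schedule` (overrides for
#'   [protocol_schedule()]), `analysis` (`threshold`, `min_duration`,
#'   `merge_gap`, `sle_min_duration`, all ms/mV; `pre_window`,
#'   `post_window` as 2-vectors in ms) and `output` (`dir`,
#'   `write_trace`).
#' @export
default_run_config <- function() {
  structure(list(
    parameters = list(),
    schedule = list(),
    analysis = list(threshold = -35, min_duration = 100, merge_gap = 200,
                    sle_min_duration = 5000,
                    pre_window = c(240000, 450000),
                    post_window = c(480000, 600000)),
    output = list(dir = ".", write_trace = TRUE)
  ), class = "run_config")
}

#' Read and validate a run configuration
#'
#' Loads a YAML configuration and merges it over [default_run_config()].
#' Unknown section or field names, and unknown model-parameter or schedule
#' names, are rejected.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides optional named list merged last (CLI flags take
#'   precedence over the file).
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  merge_section <- function(base, extra, where, known = names(base)) {
    if (is.null(extra)) return(base)
    unknown <- setdiff(names(extra), known)
    if (length(unknown))
      stop("unknown field(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    base[names(extra)] <- extra
    base
  }
  apply_cfg <- function(cfg, raw, label) {
    bad <- setdiff(names(raw), c("parameters", "schedule", "analysis",
                                 "output"))
    if (length(bad))
      stop("unknown section(s) in ", label, ": ", paste(bad, collapse = ", "))
    cfg$parameters <- merge_section(cfg$parameters, raw$parameters,
                                    "parameters",
                                    known = names(model_parameters()))
    cfg$schedule <- merge_section(cfg$schedule, raw$schedule, "schedule",
                                  known = names(protocol_schedule()))
    cfg$analysis <- merge_section(cfg$analysis, raw$analysis, "analysis")
    cfg$output <- merge_section(cfg$output, raw$output, "output")
    cfg
  }
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    cfg <- apply_cfg(cfg, raw, paste0("config '", path, "'"))
  }
  if (!is.null(overrides)) cfg <- apply_cfg(cfg, overrides, "overrides")
  structure(cfg, class = "run_config")
}

resolve_config <- function(config) {
  params <- do.call(model_parameters, config$parameters)
  sched <- do.call(protocol_schedule, config$schedule)
  list(params = params, sched = sched)
}

#' Analyze a voltage trace: events, statistics, conductance summary
#'
#' Runs discharge detection with the configured thresholds, classifies
#' seizure-like events (duration above `sle_min_duration`), and computes
#' frequency/duration statistics and mean input conductance over the pre-
#' and post-block analysis windows.  The same code path serves both
#' freshly simulated traces and traces read back from CSV, so inline and
#' offline analyses agree exactly.
#'
#' @param trace a `sim_trace`, a data frame with `time_ms` and `V_mV`
#'   (optionally `G_input_nS`), or a path to a trace CSV.
#' @param config a `run_config` (its `analysis` section is used).
#' @return A list of class `trace_analysis` with `events` (data frame),
#'   `summary` (named list: event counts, pre/post frequencies and mean
#'   durations, SLE count, mean pre/post input conductance when
#'   available).
#' @export
analyze_trace <- function(trace, config = default_run_config()) {
  if (is.character(trace)) trace <- read_trace_csv(trace)
  an <- config$analysis
  if (nrow(trace) == 0 || all(trace$V_mV < an$threshold)) {
    events <- structure(data.frame(onset = numeric(0), offset = numeric(0),
                                   duration = numeric(0),
                                   peak_V = numeric(0)),
                        class = c("discharge_events", "data.frame"))
  } else {
    events <- detect_discharges(trace$time_ms, trace$V_mV,
                                threshold = an$threshold,
                                min_duration = an$min_duration,
                                merge_gap = an$merge_gap)
  }
  win_ok <- function(w) nrow(trace) && max(trace$time_ms) >= w[1]
  stats_or_na <- function(w) {
    if (!win_ok(w))
      return(list(n = 0L, frequency_hz = NA_real_,
                  mean_duration_s = NA_real_))
    suppressWarnings(discharge_stats(events, w[1], min(w[2],
                                                       max(trace$time_ms))))
  }
  pre <- stats_or_na(an$pre_window)
  post <- stats_or_na(an$post_window)
  g_mean <- function(w) {
    if (is.null(trace$G_input_nS) || !win_ok(w)) return(NA_real_)
    sel <- trace$time_ms > w[1] & trace$time_ms <= w[2]
    mean(trace$G_input_nS[sel])
  }
  summary <- list(
    n_events = nrow(events),
    n_sle = sum(events$duration > an$sle_min_duration),
    pre_n = pre$n, pre_frequency_hz = pre$frequency_hz,
    pre_mean_duration_s = pre$mean_duration_s,
    post_n = post$n, post_frequency_hz = post$frequency_hz,
    post_mean_duration_s = post$mean_duration_s,
    pre_G_input_nS = g_mean(an$pre_window),
    post_G_input_nS = g_mean(an$post_window)
  )
  structure(list(events = events, summary = summary, analysis = an),
            class = "trace_analysis")
}

#' @export
print.trace_analysis <- function(x, ...) {
  s <- x$summary
  cat("<trace_analysis> ", s$n_events, " events (", s$n_sle,
      " seizure-like)\n", sep = "")
  cat(sprintf("  pre-block:  %s events, %.3f Hz, mean %.2f s\n",
              s$pre_n, s$pre_frequency_hz, s$pre_mean_duration_s))
  cat(sprintf("  post-block: %s events, %.3f Hz, mean %.2f s\n",
              s$post_n, s$post_frequency_hz, s$post_mean_duration_s))
  if (is.finite(s$pre_G_input_nS))
    cat(sprintf("  G_input: %.2f nS pre, %.2f nS post\n",
                s$pre_G_input_nS, s$post_G_input_nS))
  invisible(x)
}

#' Run the full in-silico experiment
#'
#' Simulates the model under the configured schedule, analyzes the trace,
#' and (optionally) writes all artifacts to the output directory: the
#' trace CSV with its YAML config echo, the detected-event CSV, and a
#' JSON summary with the pre- and post-block statistics.
#'
#' @param config a `run_config`.
#' @param write set `FALSE` to skip writing files.
#' @return The [analyze_trace()] result, with the `sim_trace` attached as
#'   attribute `trace`, invisibly.
#' @examples
#' \donttest{
#' cfg <- read_run_config(overrides = list(schedule = list(
#'   t_end_run = 5000, seed = 3)))
#' res <- run_experiment(cfg, write = FALSE)
#' res$summary$n_events
#' }
#' @export
run_experiment <- function(config = default_run_config(), write = TRUE) {
  rs <- resolve_config(config)
  trace <- run_simulation(rs$params, rs$sched)
  res <- analyze_trace(trace, config)
  if (write) {
    dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output$dir, f)
    if (isTRUE(config$output$write_trace))
      write_trace_csv(trace, out("trace.csv"))
    utils::write.csv(res$events, out("events.csv"), row.names = FALSE)
    jsonlite::write_json(res$summary, out("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(list(parameters = unclass(rs$params),
                          schedule = unclass(rs$sched),
                          analysis = config$analysis,
                          package_version = as.character(
                            utils::packageVersion("ecdischarge"))),
                     out("config_echo.yml"))
  }
  attr(res, "trace") <- trace
  invisible(res)
}
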