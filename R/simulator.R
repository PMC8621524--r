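#' Sample the Poisson shot-noise events of the noisy population
#'
#' Event times form a homogeneous Poisson process at rate `lambda_hz`
#' (drawn as exponential inter-arrival times); amplitudes are i.i.d.
#' Gaussian with mean `mu` and standard deviation `sigma`, truncated at 0
#' by redrawing (at the default 8 +/- 1.5 nS the truncation is a 5.3-sigma
#' event and essentially never fires).  Times are drawn first, then
#' amplitudes, so traces are reproducible across platforms given the seed.
#'
#' @param t_end_run run length, ms.
#' @param lambda_hz event rate, Hz.
#' @param mu,sigma amplitude mean and s.d., nS.
#' @param seed integer seed.
#' @return Data frame with columns `time` (ms, sorted, in (0, t_end_run])
#'   and `amplitude` (nS, positive).
#' @examples
#' ev <- sample_noise_events(10000, seed = 1)
#' nrow(ev)  # about 15 events in 10 s at 1.5 Hz
#' @export
sample_noise_events <- function(t_end_run, lambda_hz = 1.5, mu = 8,
                                sigma = 1.5, seed = 1L) {
  stopifnot(lambda_hz >= 0, sigma >= 0, t_end_run > 0)
  if (lambda_hz == 0)
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  set.seed(as.integer(seed))
  rate_ms <- lambda_hz / 1000
  expected <- rate_ms * t_end_run
  times <- numeric(0)
  last <- 0
  repeat {
    n_draw <- max(100L, ceiling(expected - rate_ms * last + 10 * sqrt(expected)))
    gaps <- stats::rexp(n_draw, rate_ms)
    times <- c(times, last + cumsum(gaps))
    last <- times[length(times)]
    if (last > t_end_run) break
  }
  times <- times[times <= t_end_run]
  n <- length(times)
  amp <- stats::rnorm(n, mu, sigma)
  while (any(amp <= 0))
    amp[amp <= 0] <- stats::rnorm(sum(amp <= 0), mu, sigma)
  data.frame(time = times, amplitude = amp)
}

#' One explicit Euler step of the model (pure-R reference)
#'
#' Advances all continuous variables by one step of size `dt` using
#' [model_derivatives()], applies any noise event with time in
#' `(state$t, state$t + dt]` as an instantaneous jump of the noise
#' conductance, and clamps the gate variables to [0, 1] against round-off.
#' This is the reference implementation the compiled integrator is tested
#' against; use [run_simulation()] for full runs.
#'
#' @param state a [model_state()].
#' @param dt step size, ms (<= 0.1).
#' @param sched a [protocol_schedule()].
#' @param params a [model_parameters()].
#' @param events optional data frame as returned by [sample_noise_events()].
#' @return The advanced `model_state`.
#' @export
euler_step <- function(state, dt, sched = protocol_schedule(),
                       params = model_parameters(), events = NULL) {
  if (dt > 0.1) stop("dt must not exceed 0.1 ms")
  d <- model_derivatives(state, sched, params)
  s <- state
  for (f in state_fields()) s[[f]] <- s[[f]] + dt * d[[f]]
  if (!is.null(events) && nrow(events)) {
    hit <- events$time > state$t & events$time <= state$t + dt
    if (any(hit)) s$G_noise <- s$G_noise + sum(events$amplitude[hit])
  }
  for (g in c("T_syn", "chi_syn", "chi_NMDA", "G_trans", "G_pers"))
    s[[g]] <- min(1, max(0, s[[g]]))
  s$t <- state$t + dt
  if (!all(vapply(s[state_fields()], is.finite, logical(1))))
    stop("integration failure: non-finite state at t = ", s$t)
  s
}

#' Run a full simulation
#'
#' Integrates the model from its standard initial conditions over the
#' schedule with the compiled explicit Euler integrator, applying the
#' seeded Poisson shot-noise jumps, and returns a uniformly sampled trace
#' (one row per `record_stride` steps) of all state variables together
#' with the derived quantities recomputed from the recorded state via the
#' model-core operations: the K+ and Na+ reversal potentials, pump
#' current, reciprocal and triggering conductances, transient and
#' persistent currents of the main population, and the total input
#' conductance.
#'
#' @param params a [model_parameters()].
#' @param sched a [protocol_schedule()]; its `seed` drives the noise.
#' @param init starting [model_state()]; defaults to the standard initial
#'   conditions.  Supplying e.g. a post-discharge state (elevated
#'   conductance gates and K+) supports virtual step-protocol experiments
#'   on the relaxation phase.
#' @return A data frame of class `sim_trace` with attributes `params`,
#'   `sched`, `events` (count), and `max_clamp` (largest gate clamp
#'   applied, an indicator that `dt` is too large when above 1e-6).
#' @examples
#' tr <- run_simulation(sched = protocol_schedule(t_end_run = 2000, seed = 7))
#' range(tr$V_mV)
#' @export
run_simulation <- function(params = model_parameters(),
                           sched = protocol_schedule(),
                           init = initial_state(params)) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(sched, "protocol_schedule"),
            inherits(init, "model_state"))
  ev <- sample_noise_events(sched$t_end_run, params$lambda_noise,
                            params$mu_noise, params$sigma_noise, sched$seed)
  res <- sim_core_cpp(unlist(init[state_fields()]), unclass(params),
                      unclass(sched), ev$time, ev$amplitude)
  st <- as.data.frame(res$states)
  names(st) <- c("time_ms", "V_mV", "V_noisy_mV", "G_noise_nS", "T_syn",
                 "chi_syn", "chi_NMDA", "G_trans", "G_pers", "K_out_mM",
                 "Na_in_mM")
  tr <- cbind(st, trace_derived(st, sched, params))
  attr(tr, "params") <- params
  attr(tr, "sched") <- sched
  attr(tr, "events") <- nrow(ev)
  attr(tr, "max_clamp") <- res$max_clamp
  class(tr) <- c("sim_trace", "data.frame")
  if (res$max_clamp > 1e-6)
    warning("gate clamp exceeded 1e-6 (", signif(res$max_clamp, 3),
            "); consider a smaller dt")
  tr
}

#' Derived trace quantities from recorded state
#'
#' Recomputes, column-wise from the recorded state samples, every derived
#' quantity stored in a `sim_trace`: identical model-core arithmetic, so
#' the columns are reproducible bit-for-bit from the state.
#'
#' @param st data frame of recorded state columns (names as in
#'   [run_simulation()]).
#' @param sched,params schedule and parameters of the run.
#' @return Data frame of derived columns.
#' @keywords internal
trace_derived <- function(st, sched, params) {
  state <- list(t = st$time_ms, V = st$V_mV, V_noisy = st$V_noisy_mV,
                G_noise = st$G_noise_nS, T_syn = st$T_syn,
                chi_syn = st$chi_syn, chi_NMDA = st$chi_NMDA,
                G_trans = st$G_trans, G_pers = st$G_pers,
                K_out = st$K_out_mM, Na_in = st$Na_in_mM)
  rev <- reversal_potentials(state, params)
  data.frame(
    V_K_mV = rev$V_K,
    V_Na_mV = rev$V_Na,
    I_pump_pA = pump_current(state$K_out, state$Na_in, params),
    G_recip_nS = reciprocal_conductance(state, sched, params),
    G_trig_nS = trigger_conductance(state, sched, params),
    I_trans_pA = transient_current(state$V, state, sched, params),
    I_pers_pA = persistent_current(state$V, state, sched, params),
    G_input_nS = model_input_conductance(state, sched, params)
  )
}

#' @export
print.sim_trace <- function(x, ...) {
  sched <- attr(x, "sched")
  if (is.null(sched)) return(print.data.frame(x, ...))  # subset traces
  cat("<sim_trace> ", nrow(x), " samples over ",
      sched$t_end_run / 1000, " s (seed ", sched$seed, ")\n", sep = "")
  cat("  V range [", round(min(x$V_mV), 1), ", ", round(max(x$V_mV), 1),
      "] mV; K_out range [", round(min(x$K_out_mM), 2), ", ",
      round(max(x$K_out_mM), 2), "] mM\n", sep = "")
  invisible(x)
}

#' Plot a simulation trace
#'
#' Three stacked panels: membrane voltages of both populations, total
#' input conductance, and the resource/pump variables.
#'
#' @param x a `sim_trace`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.sim_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  ts <- x$time_ms / 1000
  graphics::plot(ts, x$V_mV, type = "l", xlab = "time (s)",
                 ylab = "V (mV)", col = "black", ...)
  graphics::lines(ts, x$V_noisy_mV, col = "grey60")
  graphics::plot(ts, x$G_input_nS, type = "l", xlab = "time (s)",
                 ylab = "G_input (nS)")
  graphics::plot(ts, x$chi_syn, type = "l", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "gates")
  graphics::lines(ts, x$chi_NMDA, col = "purple")
  graphics::lines(ts, x$I_pump_pA / attr(x, "params")$Ipump_max, col = "red")
  invisible(x)
}

#' Write / read a simulation or fixture trace as CSV
#'
#' The CSV dialect has one row per sample and SI-prefixed units in the
#' column names; `time_ms` and `V_mV` are mandatory, any further columns
#' are carried through.  `write_trace_csv` also writes a YAML config echo
#' (`<path>.yml`) of the run's parameters, schedule and seed when the
#' trace carries them, so every run is reproducible from its outputs.
#'
#' @param trace a `sim_trace` or any data frame with `time_ms` and `V_mV`.
#' @param path output CSV path.
#' @param echo_config write the YAML sidecar (default TRUE for traces that
#'   carry attributes).
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a data frame.
#' @export
write_trace_csv <- function(trace, path, echo_config = TRUE) {
  stopifnot(all(c("time_ms", "V_mV") %in% names(trace)))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  params <- attr(trace, "params")
  sched <- attr(trace, "sched")
  if (echo_config && !is.null(params) && !is.null(sched)) {
    yaml::write_yaml(list(parameters = unclass(params),
                          schedule = unclass(sched),
                          package_version = as.character(
                            utils::packageVersion("ecdischarge"))),
                     paste0(path, ".yml"))
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path)
  missing_cols <- setdiff(c("time_ms", "V_mV"), names(tr))
  if (length(missing_cols))
    stop("malformed trace CSV '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(tr$time_ms))
  if (length(bad))
    stop("malformed trace CSV '", path, "': non-numeric time at row ", bad[1])
  tr
}
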