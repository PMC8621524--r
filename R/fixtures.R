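#' Generate replicate post-discharge conductance decay series
#'
#' Draws `n` noisy realizations of the single-exponential decay
#' `A_baseline + A_transient * exp(-t / tau)` at the given sample times —
#' the shape of the input-conductance relaxation measured with repeated
#' hyperpolarizing steps after a discharge.  Ground truth is returned with
#' the data so round-trip tests can assert recovery.
#'
#' @param A_baseline,A_transient,tau decay model parameters (nS, nS, ms);
#'   defaults are the published control-condition values (4.1, 1.5,
#'   920).
#' @param sample_times sampling times after the discharge, ms; the default
#'   four steps at 1-s intervals mirror the step protocol.
#' @param noise_sd additive Gaussian noise s.d., nS.
#' @param n number of replicates.
#' @param seed integer seed.
#' @return A list of class `decay_fixture`: `times`, `replicates`
#'   (n x length(times) matrix), `mean` (replicate average), and `truth`.
#' @examples
#' fx <- gen_decay_series(noise_sd = 0)
#' fx$mean[1]   # 4.1 + 1.5 exp(-500/920), about 5.0 nS
#' @export
gen_decay_series <- function(A_baseline = 4.1, A_transient = 1.5, tau = 920,
                             sample_times = c(500, 1500, 2500, 3500),
                             noise_sd = 0.1, n = 13, seed = 1L) {
  stopifnot(tau > 0, noise_sd >= 0, n >= 1)
  set.seed(as.integer(seed))
  clean <- A_baseline + A_transient * exp(-sample_times / tau)
  reps <- matrix(rep(clean, each = n), nrow = n) +
    matrix(stats::rnorm(n * length(sample_times), 0, noise_sd), nrow = n)
  structure(list(times = sample_times, replicates = reps,
                 mean = colMeans(reps),
                 truth = list(A_baseline = A_baseline,
                              A_transient = A_transient, tau = tau,
                              noise_sd = noise_sd, n = n, seed = seed)),
            class = "decay_fixture")
}

#' Generate samples of an inwardly rectifying I-V curve
#'
#' Noisy samples of `I(v) = a * f(v) * (v - V_rev)` with the Boltzmann
#' factor `f(v) = 1 / (1 + exp((v - h) / k))`, on a voltage grid spanning
#' the usual holding range.  Defaults are the published fit of the
#' post-discharge transient current (gain 2.25 nS, reversal -60.28 mV,
#' Boltzmann midpoint -65.63 mV, slope 9.82 mV).
#'
#' @param a gain, nS.
#' @param V_rev reversal potential, mV.
#' @param h,k Boltzmann midpoint and slope, mV (`k > 0`).
#' @param grid holding voltages, mV.
#' @param noise_sd additive Gaussian noise s.d., pA.
#' @param seed integer seed.
#' @return An `iv_data` data frame (columns `V`, `I`) with a `truth`
#'   attribute.
#' @examples
#' iv <- gen_iv_samples()
#' iv$I[iv$V == -27]   # about 1.44 pA
#' @export
gen_iv_samples <- function(a = 2.25, V_rev = -60.28, h = -65.63, k = 9.82,
                           grid = seq(-107, -27, by = 10), noise_sd = 0,
                           seed = 1L) {
  stopifnot(k > 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  I <- a / (1 + exp((grid - h) / k)) * (grid - V_rev) +
    stats::rnorm(length(grid), 0, noise_sd)
  out <- structure(data.frame(V = grid, I = I),
                   class = c("iv_data", "data.frame"))
  attr(out, "truth") <- list(a = a, V_rev = V_rev, h = h, k = k,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a voltage trace with implanted discharges
#'
#' Builds a synthetic current-clamp-like trace: Gaussian sample noise
#' around `baseline_V`, rectangular discharge depolarizations of known
#' onset, duration and amplitude implanted at Poisson-like onset times
#' with an enforced refractory gap (so discharges never overlap), each
#' followed by a rounded sub-threshold after-depolarization tail, plus an
#' optional implanted hyperpolarizing step-response protocol.  The
#' ground-truth event list is returned with the trace; detection
#' round-trips recover onset, offset and duration exactly up to the
#' sampling interval.
#'
#' @param rate discharge rate, Hz (the realized rate is slightly below
#'   `rate` because of the refractory gap).
#' @param duration_s trace length, s.
#' @param discharge_duration_ms duration of each rectangular discharge, ms.
#' @param discharge_amp discharge amplitude above baseline, mV.
#' @param baseline_V baseline voltage, mV (default -74.7, the
#'   hyperpolarized pre-discharge level of the steady-discharge regime).
#' @param noise_sd Gaussian sample noise s.d., mV.
#' @param adp_amp amplitude of the after-depolarization tail, mV (decays
#'   exponentially with `adp_tau`); kept well below the detection
#'   threshold.
#' @param adp_tau tail time constant, ms.
#' @param step_protocol optional list with elements `onsets` (ms),
#'   `delta_V` (mV) and `duration` (ms): implant rectangular
#'   hyperpolarizing deflections of exactly `delta_V`.
#' @param dt sampling interval, ms.
#' @param refractory_ms minimum gap between successive onsets, ms.
#' @param seed integer seed.
#' @return A list of class `voltage_trace_fixture`: `trace` (data frame
#'   `time_ms`, `V_mV`), `events` (ground-truth onsets/offsets/durations),
#'   and `truth` (all generator parameters).
#' @examples
#' fx <- gen_voltage_trace(rate = 0.21, duration_s = 60, seed = 2)
#' nrow(fx$events)
#' @export
gen_voltage_trace <- function(rate = 0.21, duration_s = 600,
                              discharge_duration_ms = 480,
                              discharge_amp = 45, baseline_V = -74.7,
                              noise_sd = 0.5, adp_amp = 8, adp_tau = 300,
                              step_protocol = NULL, dt = 1,
                              refractory_ms = NULL, seed = 1L) {
  stopifnot(rate >= 0, duration_s > 0, dt > 0)
  if (is.null(refractory_ms))
    refractory_ms <- discharge_duration_ms + 5 * adp_tau
  total_ms <- duration_s * 1000
  if (rate > 0 &&
      rate * duration_s * (discharge_duration_ms + refractory_ms) > total_ms)
    stop("infeasible discharge density: rate * duration of events exceeds the trace")
  set.seed(as.integer(seed))
  times <- seq(0, total_ms - dt, by = dt)
  V <- rep(baseline_V, length(times))
  if (noise_sd > 0) V <- V + stats::rnorm(length(times), 0, noise_sd)
  onsets <- numeric(0)
  if (rate > 0) {
    t <- 0
    rate_ms <- rate / 1000
    repeat {
      gap <- stats::rexp(1, rate_ms)
      cand <- t + gap
      if (length(onsets) && cand - onsets[length(onsets)] < refractory_ms) {
        t <- cand
        next
      }
      if (cand + discharge_duration_ms >= total_ms) break
      onsets <- c(onsets, cand)
      t <- cand
    }
    onsets <- round(onsets / dt) * dt  # align to the sample grid
  }
  n_samp <- length(times)
  for (on in onsets) {
    i0 <- floor(on / dt) + 1L
    i1 <- min(i0 + ceiling(discharge_duration_ms / dt) - 1L, n_samp)
    V[i0:i1] <- V[i0:i1] + discharge_amp
    # rounded sub-threshold after-depolarization, truncated at 8 tau
    j0 <- i1 + 1L
    j1 <- min(j0 + ceiling(8 * adp_tau / dt), n_samp)
    if (j0 <= n_samp) {
      tail_t <- times[j0:j1] - (on + discharge_duration_ms)
      V[j0:j1] <- V[j0:j1] + adp_amp * exp(-tail_t / adp_tau)
    }
  }
  if (!is.null(step_protocol)) {
    sp <- step_protocol
    stopifnot(!is.null(sp$onsets), !is.null(sp$delta_V))
    if (is.null(sp$duration)) sp$duration <- 250
    for (on in sp$onsets) {
      idx <- times >= on & times < on + sp$duration
      V[idx] <- V[idx] - sp$delta_V
    }
  }
  events <- data.frame(onset = onsets,
                       offset = onsets + discharge_duration_ms,
                       duration = rep(discharge_duration_ms,
                                      length(onsets)),
                       amplitude = rep(discharge_amp, length(onsets)))
  structure(list(trace = data.frame(time_ms = times, V_mV = V),
                 events = events,
                 truth = list(rate = rate, duration_s = duration_s,
                              discharge_duration_ms = discharge_duration_ms,
                              discharge_amp = discharge_amp,
                              baseline_V = baseline_V, noise_sd = noise_sd,
                              adp_amp = adp_amp, adp_tau = adp_tau,
                              refractory_ms = refractory_ms, dt = dt,
                              seed = seed, step_protocol = step_protocol)),
            class = "voltage_trace_fixture")
}

#' @export
print.voltage_trace_fixture <- function(x, ...) {
  cat("<voltage_trace_fixture> ", nrow(x$trace), " samples, ",
      nrow(x$events), " implanted discharges\n", sep = "")
  invisible(x)
}
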