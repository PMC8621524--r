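#' Detect epileptiform discharges in a voltage trace
#'
#' Finds maximal intervals during which the membrane voltage is at or above
#' `threshold`, merges intervals separated by less than `merge_gap`, and
#' drops events shorter than `min_duration`.  The default threshold of
#' -35 mV is the model's trigger threshold, which separates sub-threshold
#' noise from suprathreshold discharges; both duration parameters are
#' exposed because the experimental literature states no canonical rule.
#'
#' The event offset is the time of the first sample back below threshold
#' (last supra-threshold sample plus one sampling interval), so the
#' duration of a rectangular pulse spanning n samples is exactly n times
#' the sampling interval.
#'
#' @param times sample times, ms, on a uniform grid.
#' @param V membrane voltage samples, mV.
#' @param threshold detection threshold, mV.
#' @param min_duration minimum event duration, ms.
#' @param merge_gap events closer than this gap are merged, ms.
#' @return A data frame of class `discharge_events` with columns `onset`,
#'   `offset`, `duration` (ms) and `peak_V` (mV), time-ordered and
#'   non-overlapping.
#' @examples
#' t <- 0:999
#' v <- rep(-70, 1000); v[201:400] <- -20
#' detect_discharges(t, v)
#' @export
detect_discharges <- function(times, V, threshold = -35, min_duration = 100,
                              merge_gap = 200) {
  if (length(times) != length(V)) stop("times and V must have equal length")
  if (length(times) < 2) stop("need at least two samples")
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("time grid is not uniform")
  dt <- stats::median(dt)
  empty <- structure(
    data.frame(onset = numeric(0), offset = numeric(0),
               duration = numeric(0), peak_V = numeric(0)),
    class = c("discharge_events", "data.frame"))
  sup <- V >= threshold
  if (!any(sup)) return(empty)
  r <- rle(sup)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i0 <- starts[r$values]
  i1 <- ends[r$values]
  on <- times[i0]
  off <- times[i1] + dt
  # merge intervals separated by less than merge_gap
  keep_on <- on[1]; keep_off <- off[1]
  peaks <- max(V[i0[1]:i1[1]])
  if (length(on) > 1) {
    for (k in 2:length(on)) {
      if (on[k] - keep_off[length(keep_off)] < merge_gap) {
        keep_off[length(keep_off)] <- off[k]
        peaks[length(peaks)] <- max(peaks[length(peaks)], V[i0[k]:i1[k]])
      } else {
        keep_on <- c(keep_on, on[k]); keep_off <- c(keep_off, off[k])
        peaks <- c(peaks, max(V[i0[k]:i1[k]]))
      }
    }
  }
  ev <- data.frame(onset = keep_on, offset = keep_off,
                   duration = keep_off - keep_on, peak_V = peaks)
  ev <- ev[ev$duration >= min_duration, , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("discharge_events", "data.frame"))
}

#' Discharge frequency and mean duration over a time window
#'
#' Frequency is the number of events with onset inside the window divided
#' by the window length; duration is averaged over the same events.
#'
#' @param events a [detect_discharges()] result.
#' @param t_window_start,t_window_end window edges, ms; events with
#'   `t_window_start < onset <= t_window_end` are counted.
#' @return List with `n`, `frequency_hz` and `mean_duration_s`
#'   (`mean_duration_s` is `NA` with a warning when the window holds no
#'   events).
#' @export
discharge_stats <- function(events, t_window_start, t_window_end) {
  if (t_window_end <= t_window_start) stop("window length must be positive")
  sel <- events$onset > t_window_start & events$onset <= t_window_end
  n <- sum(sel)
  len_s <- (t_window_end - t_window_start) / 1000
  if (n == 0) {
    warning("no events in window; mean duration undefined")
    return(list(n = 0L, frequency_hz = 0, mean_duration_s = NA_real_))
  }
  list(n = as.integer(n), frequency_hz = n / len_s,
       mean_duration_s = mean(events$duration[sel]) / 1000)
}

#' Input conductance from a current step (Ohm's law)
#'
#' `G = I_step / delta_V`.  With the step amplitude and the voltage
#' deflection both given as magnitudes (or both signed the same way, as
#' for a hyperpolarizing step) the result is positive; pA over mV gives nS
#' directly.
#'
#' @param delta_V membrane voltage deflection, mV (non-zero).
#' @param I_step current step amplitude, pA (default 25, the standard
#'   hyperpolarizing step magnitude).
#' @return Conductance in nS; vectorized.
#' @examples
#' input_conductance(5)      # 5 nS
#' input_conductance(12.5)   # 2 nS
#' @export
input_conductance <- function(delta_V, I_step = 25) {
  if (any(delta_V == 0)) stop("delta_V must be non-zero")
  I_step / delta_V
}

#' Measure voltage deflections of current steps in a trace
#'
#' For each step onset, estimates the steady-state deflection as the mean
#' voltage over the last `plateau_ms` of the step minus the mean over the
#' `baseline_ms` immediately before the onset.
#'
#' @param times,V trace samples (uniform grid), ms and mV.
#' @param step_onsets step onset times, ms.
#' @param step_duration step length, ms.
#' @param plateau_ms plateau-averaging window at the end of the step
#'   (default 50 ms).
#' @param baseline_ms pre-step baseline window (default 50 ms).
#' @return Numeric vector of deflections (mV, negative for
#'   hyperpolarizing steps), one per onset; `NA` where the step is not
#'   fully inside the trace.
#' @export
measure_step_deflections <- function(times, V, step_onsets,
                                     step_duration = 250, plateau_ms = 50,
                                     baseline_ms = 50) {
  vapply(step_onsets, function(on) {
    pre <- times >= on - baseline_ms & times < on
    plat <- times >= on + step_duration - plateau_ms &
      times < on + step_duration
    if (!any(pre) || !any(plat)) return(NA_real_)
    mean(V[plat]) - mean(V[pre])
  }, numeric(1))
}

#' Fit a single-exponential decay to post-discharge conductance samples
#'
#' Least-squares fit of `f(t) = A_baseline + A_transient * exp(-t / tau)`
#' to input-conductance samples taken at increasing times after a
#' discharge.  Uses Levenberg-Marquardt with five deterministic starts
#' perturbed around the heuristics `A_baseline = min(G)`,
#' `A_transient = max(G) - min(G)`, `tau = span / 3`, with `tau` bounded
#' positive; the best-RSS converged fit wins.
#'
#' @param times_since_discharge sample times after discharge offset, ms
#'   (at least 4 points).
#' @param G input-conductance samples, nS.
#' @return A list of class `decay_fit` with `A_baseline`, `A_transient`,
#'   `tau_transient` (ms), `rss` (nS^2), `converged`, and `flags`
#'   (character vector; contains `"flat"` when the data carry no
#'   resolvable transient and tau is unidentifiable).
#' @examples
#' t <- c(500, 1500, 2500, 3500)
#' g <- 4.1 + 1.5 * exp(-t / 920)
#' fit_conductance_decay(t, g)$tau_transient
#' @export
fit_conductance_decay <- function(times_since_discharge, G) {
  t <- as.numeric(times_since_discharge)
  G <- as.numeric(G)
  if (length(t) != length(G)) stop("times and G must have equal length")
  if (length(t) < 4) stop("need at least 4 samples for a 3-parameter fit")
  span <- diff(range(t))
  amp0 <- max(G) - min(G)
  flat <- amp0 < 1e-8 * max(abs(G), 1e-12)
  if (flat) {
    return(structure(list(A_baseline = mean(G), A_transient = 0,
                          tau_transient = NA_real_,
                          rss = sum((G - mean(G))^2), converged = TRUE,
                          flags = "flat", data = data.frame(t = t, G = G)),
                     class = "decay_fit"))
  }
  starts <- list(
    c(A = min(G), B = amp0, tau = span / 3),
    c(A = min(G), B = amp0 * 2, tau = span / 6),
    c(A = min(G) * 0.5, B = amp0, tau = span),
    c(A = min(G), B = amp0 * 0.5, tau = span / 1.5),
    c(A = 0.9 * min(G), B = 1.5 * amp0, tau = span / 10)
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(G ~ A + B * exp(-t / tau),
                        start = as.list(s),
                        lower = c(A = 0, B = -Inf, tau = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(A_baseline = NA_real_, A_transient = NA_real_,
                          tau_transient = NA_real_, rss = NA_real_,
                          converged = FALSE, flags = "nonconvergence",
                          data = data.frame(t = t, G = G)),
                     class = "decay_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(A_baseline = unname(cf["A"]), A_transient = unname(cf["B"]),
                 tau_transient = unname(cf["tau"]), rss = best$rss,
                 converged = TRUE, flags = character(0),
                 data = data.frame(t = t, G = G)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> G(t) = A_baseline + A_transient exp(-t/tau)\n")
  cat(sprintf("  A_baseline = %.3f nS, A_transient = %.3f nS, tau = %.1f ms, rss = %.3g\n",
              x$A_baseline, x$A_transient, x$tau_transient, x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Build a baseline-subtracted current-voltage dataset
#'
#' Pairs each holding voltage with the post-discharge current minus the
#' pre-discharge baseline current at the same holding voltage, isolating
#' the transient activity-induced component, and sorts by voltage.
#'
#' @param holding_V holding voltages, mV.
#' @param I_post currents after the discharge, pA.
#' @param I_baseline currents before discharge initiation, pA.
#' @return Data frame of class `iv_data` with columns `V` and `I`, sorted
#'   by `V`.
#' @export
build_iv <- function(holding_V, I_post, I_baseline) {
  if (length(holding_V) != length(I_post) ||
      length(holding_V) != length(I_baseline))
    stop("holding_V, I_post and I_baseline must have equal length")
  if (length(holding_V) < 2) stop("need at least 2 holding voltages")
  o <- order(holding_V)
  structure(data.frame(V = holding_V[o], I = (I_post - I_baseline)[o]),
            class = c("iv_data", "data.frame"))
}

#' Fit an inwardly rectifying I-V curve
#'
#' Least-squares fit of `I(v) = a * f(v) * (v - V_rev)` with the Boltzmann
#' rectification factor `f(v) = 1 / (1 + exp((v - h) / k))`, `k > 0`.
#' Starts are deterministic heuristics (reversal from the interpolated
#' zero crossing, gain from the hyperpolarized limb, Boltzmann midpoint
#' from the voltage span) perturbed over five multi-starts.  When all
#' samples lie on one side of the zero crossing the reversal is an
#' extrapolation and the result is flagged.
#'
#' @param iv an `iv_data` (from [build_iv()] or [gen_iv_samples()]), or any
#'   data frame with columns `V` (mV) and `I` (pA); at least 5 points.
#' @return A list of class `iv_fit` with `gain_a` (nS), `V_rev` (mV),
#'   `boltz_half` (mV), `boltz_slope` (mV), `rectification_index`, `rss`
#'   (pA^2), `converged` and `flags`.
#' @examples
#' iv <- gen_iv_samples()   # noiseless published curve
#' fit_iv(iv)$V_rev
#' @export
fit_iv <- function(iv) {
  V <- iv$V; I <- iv$I
  if (is.null(V) || is.null(I)) stop("iv must have columns V and I")
  if (length(V) < 5) stop("need at least 5 points for a 4-parameter fit")
  o <- order(V); V <- V[o]; I <- I[o]
  flags <- character(0)
  # zero-crossing heuristic for the reversal potential
  Vrev0 <- zero_crossing(V, I)
  if (is.na(Vrev0)) {
    flags <- c(flags, "reversal_extrapolated")
    Vrev0 <- if (all(I <= 0)) max(V) + 5 else min(V) - 5
  }
  span <- diff(range(V))
  low <- which.min(V)
  a0 <- abs(I[low] / (V[low] - Vrev0))
  if (!is.finite(a0) || a0 <= 0) a0 <- 1
  starts <- list(
    c(a = a0, Vrev = Vrev0, h = mean(range(V)), k = span / 8),
    c(a = a0 * 2, Vrev = Vrev0, h = mean(range(V)) - span / 4, k = span / 4),
    c(a = a0, Vrev = Vrev0 + 3, h = mean(range(V)) + span / 8, k = span / 12),
    c(a = a0 * 0.5, Vrev = Vrev0 - 3, h = mean(range(V)), k = span / 6),
    c(a = a0, Vrev = Vrev0, h = stats::quantile(V, 0.25, names = FALSE),
      k = span / 10),
    # negated-gain starts: outward-rectifying or sign-flipped data
    c(a = -a0, Vrev = Vrev0, h = mean(range(V)), k = span / 8),
    c(a = -a0 * 2, Vrev = Vrev0, h = mean(range(V)) - span / 4, k = span / 4)
  )
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(I ~ a / (1 + exp((V - h) / k)) * (V - Vrev),
                        start = as.list(s),
                        lower = c(a = -Inf, Vrev = -Inf, h = -Inf, k = 0.1),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(gain_a = NA_real_, V_rev = NA_real_,
                          boltz_half = NA_real_, boltz_slope = NA_real_,
                          rectification_index = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          flags = c(flags, "nonconvergence"),
                          data = data.frame(V = V, I = I)),
                     class = "iv_fit"))
  }
  cf <- stats::coef(best$fit)
  out <- structure(list(gain_a = unname(cf["a"]), V_rev = unname(cf["Vrev"]),
                        boltz_half = unname(cf["h"]),
                        boltz_slope = unname(cf["k"]),
                        rectification_index = NA_real_, rss = best$rss,
                        converged = TRUE, flags = flags,
                        data = data.frame(V = V, I = I)),
                   class = "iv_fit")
  ri <- tryCatch(rectification_index(out), warning = function(w) NA_real_,
                 error = function(e) NA_real_)
  out$rectification_index <- ri
  out
}

#' @export
print.iv_fit <- function(x, ...) {
  cat("<iv_fit> I(v) = a f(v) (v - V_rev), f = Boltzmann\n")
  cat(sprintf("  a = %.3f nS, V_rev = %.2f mV, half = %.2f mV, slope = %.2f mV\n",
              x$gain_a, x$V_rev, x$boltz_half, x$boltz_slope))
  cat(sprintf("  rectification index = %.3f, rss = %.3g\n",
              x$rectification_index, x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Rectification index of an I-V relationship
#'
#' Ratio of the slope of a straight line fitted to the points above the
#' reversal potential to the slope fitted below it; 1 for a linear I-V,
#' below 1 for inward rectification.  Each side needs at least two points.
#'
#' @param x an `iv_fit` (uses its data and fitted reversal), or a data
#'   frame with columns `V` and `I`.
#' @param V_rev reversal potential, mV; taken from the fit when `x` is an
#'   `iv_fit`, otherwise estimated from the interpolated zero crossing
#'   when omitted.
#' @return Dimensionless slope ratio; `NA` with a warning when either side
#'   has fewer than two points.
#' @examples
#' iv <- data.frame(V = seq(-80, -40, 10), I = seq(-80, -40, 10) + 60)
#' rectification_index(iv)   # linear curve: 1
#' @export
rectification_index <- function(x, V_rev = NULL) {
  if (inherits(x, "iv_fit")) {
    if (is.null(V_rev)) V_rev <- x$V_rev
    dat <- x$data
  } else {
    dat <- as.data.frame(x)
    if (is.null(dat$V) || is.null(dat$I)) stop("x must have columns V and I")
    if (is.null(V_rev)) {
      V_rev <- zero_crossing(dat$V, dat$I)
      if (is.na(V_rev))
        stop("cannot locate the zero crossing; supply V_rev")
    }
  }
  above <- dat$V > V_rev
  if (sum(above) < 2 || sum(!above) < 2) {
    warning("need at least two points on each side of V_rev")
    return(NA_real_)
  }
  s_pos <- stats::coef(stats::lm(I ~ V, data = dat[above, ]))[["V"]]
  s_neg <- stats::coef(stats::lm(I ~ V, data = dat[!above, ]))[["V"]]
  s_pos / s_neg
}

# Interpolated zero crossing of an I-V sample set; NA when all points lie
# on one side.  An exact zero sample wins outright.
zero_crossing <- function(V, I) {
  o <- order(V); V <- V[o]; I <- I[o]
  z <- which(I == 0)
  if (length(z)) return(V[z[1]])
  sgn <- sign(I)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(cross)) return(NA_real_)
  j <- cross[1]
  V[j] - I[j] * (V[j + 1] - V[j]) / (I[j + 1] - I[j])
}

#' Current following each discharge at a fixed delay
#'
#' Samples the (baseline-subtracted) current a fixed delay after each
#' discharge offset — the standard quantification of the slow
#' after-depolarization current.  The baseline is the mean current over
#' `baseline_ms` immediately before the event onset; the post-discharge
#' value is taken at the sample nearest to `offset + delay`.  Events whose
#' sampling point falls beyond the trace are skipped with a message.
#'
#' @param times,I trace samples (uniform grid), ms and pA.
#' @param events a [detect_discharges()] result (columns `onset`,
#'   `offset`).
#' @param delay delay after the event offset, ms (default 1500).
#' @param baseline_ms pre-onset baseline window, ms.
#' @return Data frame with one row per retained event: `onset`, `offset`,
#'   `I_post_pA` (baseline-subtracted).
#' @export
post_discharge_current <- function(times, I, events, delay = 1500,
                                   baseline_ms = 100) {
  if (delay <= 0) stop("delay must be positive")
  if (length(times) != length(I)) stop("times and I must have equal length")
  keep <- events$offset + delay <= max(times)
  if (any(!keep))
    message(sum(!keep), " event(s) too close to the trace end; skipped")
  ev <- events[keep, , drop = FALSE]
  val <- vapply(seq_len(nrow(ev)), function(k) {
    pre <- times >= ev$onset[k] - baseline_ms & times < ev$onset[k]
    base <- if (any(pre)) mean(I[pre]) else 0
    idx <- which.min(abs(times - (ev$offset[k] + delay)))
    I[idx] - base
  }, numeric(1))
  data.frame(onset = ev$onset, offset = ev$offset, I_post_pA = val)
}
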