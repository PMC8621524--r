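# Shared protocol shortcuts for tests.

# No noise window, no drug block: pure leak/pump/ion dynamics.
sched_quiet <- function(t_end_run = 10000, dt = 0.05, seed = 1L, ...) {
  protocol_schedule(t_end_run = t_end_run, dt = dt, seed = seed,
                    t_start_window = 1e15, t_end_window = 2e15,
                    t_block = Inf, ...)
}

# Activity-dependent conductance window held open for the whole run,
# no drug block (window sigmoids fully saturated: W = 1 exactly).
sched_window_on <- function(t_end_run = 10000, dt = 0.05, seed = 1L, ...) {
  protocol_schedule(t_end_run = t_end_run, dt = dt, seed = seed,
                    t_start_window = -1e9, t_end_window = 1e9,
                    t_block = Inf, ...)
}

# A plausible early-relaxation state shortly after a discharge: elevated
# conductance gates and extracellular K+, partly depleted fast resource.
post_discharge_state <- function() {
  model_state(t = 0, V = -70, V_noisy = -70, G_noise = 0, T_syn = 0,
              chi_syn = 0.5, chi_NMDA = 0.9, G_trans = 0.8, G_pers = 0.4,
              K_out = 3.5, Na_in = 14)
}

# Discharge detection with the package defaults, straight from a trace.
detect_default <- function(trace) {
  detect_discharges(trace$time_ms, trace$V_mV)
}
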