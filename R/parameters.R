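#' Model parameters for the two-population discharge model
#'
#' Constructs the full parameter set of the mean-field model with its
#' published defaults.  Conductances are in nS, capacitance in pF, voltages
#' in mV, times in ms, rates in 1/ms (ion release rates in mM/ms), currents
#' in pA and concentrations in mM.  Any parameter can be overridden by name;
#' unknown names are rejected.
#'
#' The parameter set covers: passive leak conductances for K+, Na+ and Cl-;
#' the triggering and reciprocal glutamatergic conductances (`g_trig`,
#' `g_Glut`) with their AMPA/NMDA split; the transient and persistent
#' activity-dependent conductances (`g_trans`, `g_pers`) with the ionic
#' weights `m_K`/`m_Na` of the transient current; the Na+/K+ pump maximum
#' current and half-activation constants; kinetic constants of the synaptic
#' resource, NMDA availability, conductance-gate and ion equations; and the
#' shot-noise statistics (`mu_noise`, `sigma_noise` in nS, `lambda_noise` in
#' Hz) of the spontaneously bursting population.
#'
#' @param ... named parameter overrides.
#' @return A list of class `model_parameters`.
#' @examples
#' p <- model_parameters()
#' p$g_K_leak
#' model_parameters(g_trig = 0)$g_trig
#' @export
model_parameters <- function(...) {
  p <- list(
    # passive membrane
    C = 100,            # pF
    g_K_leak = 1.9,     # nS
    g_Na_leak = 0.4,    # nS
    g_Cl_leak = 0.7,    # nS
    V_Glut = 0,         # mV, reversal of glutamatergic currents
    # synaptic and activity-dependent conductances
    g_trig = 9.5,       # nS, triggering input from the noisy population
    g_Glut = 30,        # nS, reciprocal glutamatergic input
    g_trans = 2,        # nS, transient activity-dependent conductance
    g_pers = 2,         # nS, persistent (K+) activity-dependent conductance
    m_K = 0.8,          # ionic weights of the transient current
    m_Na = 0.2,
    ampa_fraction = 0.33,
    nmda_fraction = 0.67,
    block_fraction = 0.3,   # fraction of AMPAR conductance removed by the drug
    # Na+/K+ pump
    Ipump_max = 23,     # pA
    pump_K_half = 3.5,  # mM
    pump_Na_half = 25,  # mM
    pump_Na_slope = 3,  # mM
    # kinetics
    tau_noise = 25,     # ms, decay of the shot-noise conductance
    tau_T = 25,         # ms, trigger transduction
    tau_rs = 1500,      # ms, recovery of the fast synaptic resource
    tau_rN = 52000,     # ms, recovery of NMDA availability
    tau_tr = 920,       # ms, decay of the transient conductance gate
    tau_pers = 35000,   # ms, decay of the persistent conductance gate
    tau_K = 7500,       # ms, extracellular K+ relaxation
    tau_Na = 52000,     # ms, intracellular Na+ relaxation
    r_rs = 0.003,       # 1/ms, use-dependent depletion of the synaptic resource
    r_rN = 0.00007,     # 1/ms, use-dependent NMDA downregulation
    r_trans = 0.03,     # 1/ms, activation of the transient gate
    r_pers = 0.00065,   # 1/ms, activation of the persistent gate
    r_K = 0.0017,       # mM/ms, activity-driven K+ release
    r_Na = 0.0016,      # mM/ms, activity-driven Na+ entry
    # noise statistics of the triggering population
    mu_noise = 8,       # nS, mean shot amplitude
    sigma_noise = 1.5,  # nS, shot amplitude s.d.
    lambda_noise = 1.5, # Hz, Poisson event rate
    # volumes and physical constants
    gamma_vol = 5,      # intracellular : extracellular volume ratio
    v_extracell = 300,  # um^3, extracellular volume per neuron
    faraday = 96485,    # C/mol
    nernst_scale = 26.1, # mV
    # fixed ion concentrations and resting dynamical ion values
    K_in = 140,         # mM
    Na_out = 151,       # mM
    Cl_in = 10,         # mM
    Cl_out = 133,       # mM
    K_bath = 2.5,       # mM, extracellular K+ rest level
    Na_rest = 10,       # mM, intracellular Na+ rest level
    # sigmoid shapes
    boltz_half = -65.63,   # mV, transient-current rectification midpoint
    boltz_slope = 9.82,    # mV
    nu_half = -30,         # mV, main-population rate function midpoint
    nu_slope = 0.286,      # 1/mV
    nuN_threshold = -35,   # mV, step threshold of the noisy population
    nmda_half = -47.77,    # mV, NMDA Mg-block relief midpoint
    nmda_slope = 0.06      # 1/mV
  )
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(names(override) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(override), names(p))
    if (length(unknown))
      stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
    p[names(override)] <- override
  }
  validate_model_parameters(structure(p, class = "model_parameters"))
}

validate_model_parameters <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all model parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!num], collapse = ", "))
  nonneg <- c("C", "g_K_leak", "g_Na_leak", "g_Cl_leak", "g_trig", "g_Glut",
              "g_trans", "g_pers", "Ipump_max", "tau_noise", "tau_T", "tau_rs",
              "tau_rN", "tau_tr", "tau_pers", "tau_K", "tau_Na", "r_rs",
              "r_rN", "r_trans", "r_pers", "r_K", "r_Na", "sigma_noise",
              "lambda_noise", "gamma_vol", "v_extracell")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad))
    stop("parameters must be non-negative: ", paste(bad, collapse = ", "))
  if (abs(p$m_K + p$m_Na - 1) > 1e-10)
    stop("m_K + m_Na must equal 1")
  if (abs(p$ampa_fraction + p$nmda_fraction - 1) > 1e-10)
    stop("ampa_fraction + nmda_fraction must equal 1")
  if (p$block_fraction < 0 || p$block_fraction > 1)
    stop("block_fraction must lie in [0, 1]")
  pos <- c("K_in", "Na_out", "Cl_in", "Cl_out", "K_bath", "Na_rest",
           "boltz_slope")
  badp <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(badp))
    stop("parameters must be strictly positive: ", paste(badp, collapse = ", "))
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters> ", length(x), " constants\n", sep = "")
  cat("  leak K/Na/Cl: ", x$g_K_leak, "/", x$g_Na_leak, "/", x$g_Cl_leak,
      " nS; g_trig = ", x$g_trig, " nS; g_Glut = ", x$g_Glut, " nS\n", sep = "")
  cat("  g_trans = ", x$g_trans, " nS; g_pers = ", x$g_pers,
      " nS; Ipump_max = ", x$Ipump_max, " pA\n", sep = "")
  cat("  noise: mu = ", x$mu_noise, " nS, sigma = ", x$sigma_noise,
      " nS, lambda = ", x$lambda_noise, " Hz\n", sep = "")
  invisible(x)
}

#' Protocol schedule of a simulation run
#'
#' Defines the timing of a run: total duration and step size, the sigmoid
#' time window gating the activity-dependent conductances (their emergence
#' after the initial seizure-like event and their removal by the simulated
#' drug), the onset time of the AMPAR block, the random seed, recording
#' stride, and an optional hyperpolarizing current-step protocol applied to
#' the main population for virtual input-conductance measurements.
#'
#' Infinite window or block times are legal and disable the corresponding
#' mechanism smoothly: `t_block = Inf` means no drug block,
#' `t_start_window = Inf` keeps the activity-dependent conductances off,
#' `t_start_window = -Inf` together with `t_end_window = Inf` keeps them
#' permanently enabled.
#'
#' @param t_end_run run length, ms.
#' @param dt integration step, ms (must be <= 0.1).
#' @param t_start_window,t_end_window window edges for the activity-dependent
#'   conductances, ms.
#' @param t_block half-maximal time of the AMPAR block sigmoid, ms.
#' @param block_sigmoid_tau,window_sigmoid_tau sigmoid time scales, ms.
#' @param seed integer seed for the noise process.
#' @param nmda_scale multiplier on the NMDA term of the reciprocal input
#'   (default 1 reproduces the unperturbed model; < 1 emulates NMDAR block).
#' @param record_stride record every `record_stride`-th step (default 20,
#'   i.e. 1-ms sampling at dt = 0.05 ms).
#' @param step_onsets onset times (ms) of injected current steps, main
#'   population only.
#' @param step_amp injected step amplitude, pA (negative = hyperpolarizing).
#' @param step_duration step duration, ms.
#' @return A list of class `protocol_schedule`.
#' @examples
#' protocol_schedule(t_end_run = 10000, seed = 42)
#' @export
protocol_schedule <- function(t_end_run = 600000, dt = 0.05,
                              t_start_window = 120000, t_end_window = 480000,
                              t_block = 450000,
                              block_sigmoid_tau = 15000,
                              window_sigmoid_tau = 10000,
                              seed = 1L, nmda_scale = 1, record_stride = 20L,
                              step_onsets = numeric(0), step_amp = -25,
                              step_duration = 250) {
  s <- list(t_end_run = t_end_run, dt = dt,
            t_start_window = t_start_window, t_end_window = t_end_window,
            t_block = t_block, block_sigmoid_tau = block_sigmoid_tau,
            window_sigmoid_tau = window_sigmoid_tau,
            seed = as.integer(seed), nmda_scale = nmda_scale,
            record_stride = as.integer(record_stride),
            step_onsets = sort(as.numeric(unlist(step_onsets))),
            step_amp = step_amp, step_duration = step_duration)
  if (!is.finite(s$dt) || s$dt <= 0) stop("dt must be positive")
  if (s$dt > 0.1) stop("dt must not exceed 0.1 ms (explicit Euler accuracy)")
  if (!is.finite(s$t_end_run) || s$t_end_run <= 0)
    stop("t_end_run must be positive and finite")
  if (!(s$t_start_window < s$t_end_window))
    stop("t_start_window must be smaller than t_end_window")
  if (s$record_stride < 1L) stop("record_stride must be >= 1")
  if (s$step_duration <= 0) stop("step_duration must be positive")
  if (length(s$step_onsets) > 1 &&
      any(diff(s$step_onsets) < s$step_duration))
    stop("current steps must not overlap")
  structure(s, class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat("<protocol_schedule> ", x$t_end_run / 1000, " s, dt = ", x$dt,
      " ms, seed = ", x$seed, "\n", sep = "")
  cat("  window [", x$t_start_window / 1000, ", ", x$t_end_window / 1000,
      "] s; block at ", x$t_block / 1000, " s\n", sep = "")
  if (length(x$step_onsets))
    cat("  ", length(x$step_onsets), " injected steps of ", x$step_amp,
        " pA, ", x$step_duration, " ms\n", sep = "")
  invisible(x)
}

#' Model state at one instant
#'
#' The ten dynamical variables of the model plus time.  Gate variables
#' (`T_syn`, `chi_syn`, `chi_NMDA`, `G_trans`, `G_pers`) live in [0, 1],
#' the noise conductance is non-negative, and the dynamical ion
#' concentrations are strictly positive.
#'
#' @param t time, ms.
#' @param V,V_noisy membrane voltages of the main and noisy populations, mV.
#' @param G_noise shot-noise conductance, nS.
#' @param T_syn trigger transduction variable, dimensionless.
#' @param chi_syn,chi_NMDA fast synaptic resource and NMDA availability.
#' @param G_trans,G_pers transient and persistent conductance gates.
#' @param K_out extracellular K+, mM.
#' @param Na_in intracellular Na+, mM.
#' @return A list of class `model_state`.
#' @examples
#' initial_state()
#' @export
model_state <- function(t = 0, V = -70.4, V_noisy = -70.4, G_noise = 0,
                        T_syn = 0, chi_syn = 1, chi_NMDA = 1,
                        G_trans = 0, G_pers = 0, K_out = 2.5, Na_in = 10) {
  s <- list(t = t, V = V, V_noisy = V_noisy, G_noise = G_noise,
            T_syn = T_syn, chi_syn = chi_syn, chi_NMDA = chi_NMDA,
            G_trans = G_trans, G_pers = G_pers, K_out = K_out, Na_in = Na_in)
  gates <- c("T_syn", "chi_syn", "chi_NMDA", "G_trans", "G_pers")
  for (g in gates)
    if (any(s[[g]] < 0 | s[[g]] > 1))
      stop(g, " must lie in [0, 1]")
  if (any(s$G_noise < 0)) stop("G_noise must be non-negative")
  if (any(s$K_out <= 0) || any(s$Na_in <= 0))
    stop("ion concentrations must be strictly positive")
  structure(s, class = "model_state")
}

#' Initial conditions of the model
#'
#' Both populations start at -70.4 mV with all gates at rest, the synaptic
#' resources full, extracellular K+ at the bath level and intracellular Na+
#' at its resting value.
#'
#' @param params a [model_parameters()] object (supplies the resting ion
#'   levels).
#' @return A `model_state`.
#' @export
initial_state <- function(params = model_parameters()) {
  model_state(t = 0, V = -70.4, V_noisy = -70.4, G_noise = 0, T_syn = 0,
              chi_syn = 1, chi_NMDA = 1, G_trans = 0, G_pers = 0,
              K_out = params$K_bath, Na_in = params$Na_rest)
}

# order of the dynamical fields used by the integrator and tests
state_fields <- function() {
  c("V", "V_noisy", "G_noise", "T_syn", "chi_syn", "chi_NMDA",
    "G_trans", "G_pers", "K_out", "Na_in")
}
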