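#' Nernst equilibrium potential
#'
#' `scale * ln(c_out / c_in)`.  For K+ and Na+ pass (outside, inside); for
#' Cl- the conventional sign is obtained by passing (inside, outside).
#'
#' @param c_out,c_in concentrations, mM; strictly positive.
#' @param scale thermal voltage scale, mV (default 26.1).
#' @return Potential in mV; vectorized.
#' @examples
#' nernst_potential(2.5, 140)   # K+ at rest, about -105 mV
#' nernst_potential(151, 10)    # Na+ at rest, about +71 mV
#' @export
nernst_potential <- function(c_out, c_in, scale = 26.1) {
  if (any(c_out <= 0) || any(c_in <= 0))
    stop("concentrations must be strictly positive")
  scale * log(c_out / c_in)
}

#' Reversal potentials at a given ionic state
#'
#' @param state a [model_state()] (or any list/data frame with `K_out` and
#'   `Na_in` fields).
#' @param params a [model_parameters()].
#' @return List with components `V_K`, `V_Na`, `V_Cl` (mV).
#' @export
reversal_potentials <- function(state, params = model_parameters()) {
  list(V_K = nernst_potential(state$K_out, params$K_in, params$nernst_scale),
       V_Na = nernst_potential(params$Na_out, state$Na_in, params$nernst_scale),
       V_Cl = nernst_potential(params$Cl_in, params$Cl_out, params$nernst_scale))
}

#' Na+/K+ pump current
#'
#' Electrogenic pump current as a product of two sigmoid activation terms in
#' extracellular K+ and intracellular Na+, saturating at `Ipump_max`.
#'
#' @param K_out extracellular K+, mM.
#' @param Na_in intracellular Na+, mM.
#' @param params a [model_parameters()].
#' @return Current in pA (outward positive); vectorized.
#' @examples
#' pump_current(2.5, 10)  # near-silent at rest
#' @export
pump_current <- function(K_out, Na_in, params = model_parameters()) {
  params$Ipump_max /
    ((1 + exp(params$pump_K_half - K_out)) *
       (1 + exp((params$pump_Na_half - Na_in) / params$pump_Na_slope)))
}

#' NMDA magnesium-block relief function
#'
#' Sigmoid fraction of the NMDAR conductance relieved from Mg2+ block at
#' voltage `V`; equals 1/2 at `nmda_half` (-47.77 mV under the low-Mg2+
#' proepileptic solution).
#'
#' @param V membrane voltage, mV.
#' @param params a [model_parameters()].
#' @return Value in (0, 1); vectorized.
#' @export
f_nmda <- function(V, params = model_parameters()) {
  1 / (1 + exp(params$nmda_slope * (params$nmda_half - V)))
}

#' Firing-rate function of the main population
#'
#' Sigmoid input-output function, half-maximal at `nu_half` (-30 mV).
#'
#' @inheritParams f_nmda
#' @return Value in (0, 1); vectorized.
#' @export
nu_main <- function(V, params = model_parameters()) {
  1 / (1 + exp(params$nu_slope * (params$nu_half - V)))
}

#' Step input-output function of the noisy population
#'
#' Unit step at `nuN_threshold` (-35 mV): 0 below, 1 at or above.
#'
#' @param V_noisy membrane voltage of the noisy population, mV.
#' @param params a [model_parameters()].
#' @return 0 or 1; vectorized.
#' @export
nu_noisy <- function(V_noisy, params = model_parameters()) {
  as.numeric(V_noisy >= params$nuN_threshold)
}

#' Scheduled AMPAR block function
#'
#' Sigmoid reduction of the AMPAR-mediated conductance by `block_fraction`
#' (default 30 %), half-maximal at `t_block`; ranges from 1 long before the
#' block to `1 - block_fraction` long after.
#'
#' @param t time, ms.
#' @param sched a [protocol_schedule()].
#' @param params a [model_parameters()].
#' @return Dimensionless factor; vectorized in `t`.
#' @export
f_block <- function(t, sched = protocol_schedule(),
                    params = model_parameters()) {
  1 - params$block_fraction /
    (1 + exp((-t + sched$t_block) / sched$block_sigmoid_tau))
}

#' Time window gating the activity-dependent conductances
#'
#' Product of two sigmoids opening near `t_start_window` and closing near
#' `t_end_window`; approximately 1 deep inside the window and 0 outside.
#'
#' @param t time, ms.
#' @param sched a [protocol_schedule()].
#' @return Dimensionless gate in (0, 1); vectorized in `t`.
#' @export
window_gate <- function(t, sched = protocol_schedule()) {
  tau <- sched$window_sigmoid_tau
  (1 / (1 + exp((-t + sched$t_start_window) / tau))) *
    (1 - 1 / (1 + exp((-t + sched$t_end_window) / tau)))
}

#' Voltage dependence of the transient activity-dependent current
#'
#' Boltzmann factor describing the inward rectification of the transient
#' conductance: decreasing in `V`, half-maximal at `boltz_half`
#' (-65.63 mV) with slope `boltz_slope` (9.82 mV).
#'
#' @inheritParams f_nmda
#' @return Value in (0, 1); vectorized.
#' @export
f_trans <- function(V, params = model_parameters()) {
  1 / (1 + exp((V - params$boltz_half) / params$boltz_slope))
}

#' Triggering conductance from the noisy population
#'
#' `g_trig * T_syn * chi_syn * f_block(t)`: the glutamatergic drive the
#' noisy population exerts on the main one, gated by the trigger
#' transduction variable, the shared synaptic resource, and the drug block.
#'
#' @param state a [model_state()].
#' @param sched a [protocol_schedule()].
#' @param params a [model_parameters()].
#' @return Conductance in nS.
#' @export
trigger_conductance <- function(state, sched = protocol_schedule(),
                                params = model_parameters()) {
  params$g_trig * state$T_syn * state$chi_syn * f_block(state$t, sched, params)
}

#' Reciprocal glutamatergic conductance of the main population
#'
#' AMPA plus NMDA recurrent input:
#' `g_Glut * (ampa_fraction * f_block(t) + nmda_fraction * nmda_scale *
#' f_nmda(V) * chi_NMDA) * chi_syn * nu(V)`.  The AMPA term is reduced by
#' the scheduled block; the NMDA term is gated by its availability
#' `chi_NMDA` and the Mg2+-block relief; both share the fast synaptic
#' resource and the population firing rate.
#'
#' @inheritParams trigger_conductance
#' @return Conductance in nS, in `[0, g_Glut]`.
#' @export
reciprocal_conductance <- function(state, sched = protocol_schedule(),
                                   params = model_parameters()) {
  params$g_Glut *
    (params$ampa_fraction * f_block(state$t, sched, params) +
       params$nmda_fraction * sched$nmda_scale *
         f_nmda(state$V, params) * state$chi_NMDA) *
    state$chi_syn * nu_main(state$V, params)
}

#' Transient activity-dependent current
#'
#' `g_trans * [m_K (U - V_K) + m_Na (U - V_Na)] * f_trans(U) * G_trans * W(t)`
#' evaluated at the voltage `U` of either population; reverses at
#' `m_K V_K + m_Na V_Na` (about -70 mV at baseline ions, depolarizing
#' towards -60 mV as K+ accumulates).
#'
#' @param U membrane voltage of either population, mV.
#' @inheritParams trigger_conductance
#' @return Current in pA (outward positive).
#' @export
transient_current <- function(U, state, sched = protocol_schedule(),
                              params = model_parameters()) {
  rev <- reversal_potentials(state, params)
  params$g_trans *
    (params$m_K * (U - rev$V_K) + params$m_Na * (U - rev$V_Na)) *
    f_trans(U, params) * state$G_trans * window_gate(state$t, sched)
}

#' Persistent activity-dependent current
#'
#' `g_pers * G_pers * (U - V_K) * W(t)`: a pure K+ current, reversing
#' exactly at the K+ Nernst potential.
#'
#' @inheritParams transient_current
#' @return Current in pA (outward positive).
#' @export
persistent_current <- function(U, state, sched = protocol_schedule(),
                               params = model_parameters()) {
  V_K <- nernst_potential(state$K_out, params$K_in, params$nernst_scale)
  params$g_pers * state$G_pers * (U - V_K) * window_gate(state$t, sched)
}

#' Injected current of the step protocol
#'
#' Returns the current injected into the main population at time `t` under
#' the schedule's hyperpolarizing step protocol (0 outside the steps).
#'
#' @param t time, ms.
#' @param sched a [protocol_schedule()].
#' @return Current in pA (positive = depolarizing); vectorized in `t`.
#' @export
injected_current <- function(t, sched = protocol_schedule()) {
  if (!length(sched$step_onsets)) return(rep(0, length(t)))
  on <- vapply(t, function(tt)
    any(tt >= sched$step_onsets & tt < sched$step_onsets + sched$step_duration),
    logical(1))
  ifelse(on, sched$step_amp, 0)
}

#' Time derivatives of the model state
#'
#' Assembles the right-hand side of the full system: current balance of the
#' two membrane voltages (leaks, pump, triggering and reciprocal
#' glutamatergic input or shot-noise conductance, transient and persistent
#' currents), the drift of the noise conductance (the Poisson jumps are
#' handled by the integrator), the trigger transduction, the two synaptic
#' resources, the two conductance gates, and the two dynamical ion
#' concentrations with the pump flux converted from pA to mM/ms via the
#' Faraday constant and the relevant compartment volume.
#'
#' All shared variables (ions, gates, resources) are global: both
#' populations see the same values, and only the firing rate of the main
#' population drives the resource, gate and ion equations.
#'
#' @param state a [model_state()].
#' @param sched a [protocol_schedule()].
#' @param params a [model_parameters()].
#' @return Named numeric vector of d(state)/dt over the ten dynamical
#'   fields, in units per ms.
#' @examples
#' d <- model_derivatives(initial_state())
#' d[["chi_syn"]]  # 0 at full resource with no firing
#' @export
model_derivatives <- function(state, sched = protocol_schedule(),
                              params = model_parameters()) {
  p <- params
  s <- state
  rev <- reversal_potentials(s, p)
  Ip <- pump_current(s$K_out, s$Na_in, p)
  W <- window_gate(s$t, sched)
  nu <- nu_main(s$V, p)
  nuN <- nu_noisy(s$V_noisy, p)
  G_trig <- trigger_conductance(s, sched, p)
  G_rec <- reciprocal_conductance(s, sched, p)
  itrans <- function(U)
    p$g_trans * (p$m_K * (U - rev$V_K) + p$m_Na * (U - rev$V_Na)) *
      f_trans(U, p) * s$G_trans * W
  ipers <- function(U) p$g_pers * s$G_pers * (U - rev$V_K) * W
  I_inj <- injected_current(s$t, sched)

  dV <- -(p$g_K_leak * (s$V - rev$V_K) +
            p$g_Na_leak * (s$V - rev$V_Na) +
            p$g_Cl_leak * (s$V - rev$V_Cl) +
            Ip + (G_trig + G_rec) * (s$V - p$V_Glut) +
            itrans(s$V) + ipers(s$V) - I_inj) / p$C
  dVn <- -(p$g_K_leak * (s$V_noisy - rev$V_K) +
             p$g_Na_leak * (s$V_noisy - rev$V_Na) +
             p$g_Cl_leak * (s$V_noisy - rev$V_Cl) +
             Ip + s$G_noise * (s$V_noisy - p$V_Glut) +
             itrans(s$V_noisy) + ipers(s$V_noisy)) / p$C
  dGn <- -s$G_noise / p$tau_noise
  dT <- nuN * (1 - s$T_syn) - s$T_syn / p$tau_T
  dxs <- -p$r_rs * nu * s$chi_syn + (1 - s$chi_syn) / p$tau_rs
  dxN <- -p$r_rN * nu * s$chi_NMDA + (1 - s$chi_NMDA) / p$tau_rN
  dGt <- p$r_trans * nu * s$chi_syn * (1 - s$G_trans) - s$G_trans / p$tau_tr
  dGp <- p$r_pers * nu * s$chi_syn * (1 - s$G_pers) - s$G_pers / p$tau_pers
  conv <- pump_flux_factor(p)  # pA -> mM/ms in the extracellular space
  dK <- p$r_K * nu - 2 * Ip * conv + (p$K_bath - s$K_out) / p$tau_K
  dNa <- p$r_Na * nu - 3 * Ip * conv / p$gamma_vol +
    (p$Na_rest - s$Na_in) / p$tau_Na
  c(V = dV, V_noisy = dVn, G_noise = dGn, T_syn = dT, chi_syn = dxs,
    chi_NMDA = dxN, G_trans = dGt, G_pers = dGp, K_out = dK, Na_in = dNa)
}

#' Conversion factor from pump current to concentration flux
#'
#' One pA flowing into the extracellular volume `v` (um^3) changes the
#' concentration there by `1e-12 / (F * v * 1e-15)` mol/(L s), which is
#' numerically equal to the same value in mM/ms.
#'
#' @param params a [model_parameters()].
#' @return Factor in mM/ms per pA of pump current.
#' @export
pump_flux_factor <- function(params = model_parameters()) {
  1e-12 / (params$faraday * params$v_extracell * 1e-15)
}

#' Total input conductance of the model
#'
#' Sum of the three leak conductances plus the windowed activity-dependent
#' terms `W(t) * [g_trans f_trans(V) G_trans + g_pers G_pers]`.  This is the
#' model-side counterpart of the experimental input-conductance estimate
#' from hyperpolarizing current steps ([input_conductance()]).
#'
#' @inheritParams trigger_conductance
#' @return Conductance in nS.
#' @export
model_input_conductance <- function(state, sched = protocol_schedule(),
                                    params = model_parameters()) {
  p <- params
  p$g_K_leak + p$g_Na_leak + p$g_Cl_leak +
    window_gate(state$t, sched) *
      (p$g_trans * f_trans(state$V, p) * state$G_trans +
         p$g_pers * state$G_pers)
}
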