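// Explicit Euler integrator for the two-population discharge model.
// Mirrors the pure-R right-hand side in R/model-core.R exactly; tests
// assert agreement of a single step to <= 1e-12 relative.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_core_cpp(NumericVector init, List par, List sch,
                  NumericVector ev_time, NumericVector ev_amp) {
  // parameters
  const double C = par["C"], gK = par["g_K_leak"], gNa = par["g_Na_leak"],
    gCl = par["g_Cl_leak"], Vglut = par["V_Glut"], gtrig = par["g_trig"],
    gGlut = par["g_Glut"], gtrans = par["g_trans"], gpers = par["g_pers"],
    mK = par["m_K"], mNa = par["m_Na"], fampa = par["ampa_fraction"],
    fnmda_frac = par["nmda_fraction"], block_frac = par["block_fraction"],
    ipmax = par["Ipump_max"], pKh = par["pump_K_half"],
    pNah = par["pump_Na_half"], pNas = par["pump_Na_slope"],
    tau_noise = par["tau_noise"], tauT = par["tau_T"],
    tau_rs = par["tau_rs"], tau_rN = par["tau_rN"], tau_tr = par["tau_tr"],
    tau_pers = par["tau_pers"], tauK = par["tau_K"], tauNa = par["tau_Na"],
    r_rs = par["r_rs"], r_rN = par["r_rN"], r_trans = par["r_trans"],
    r_pers = par["r_pers"], rK = par["r_K"], rNa = par["r_Na"],
    gamma_vol = par["gamma_vol"], vol = par["v_extracell"],
    faraday = par["faraday"], scale = par["nernst_scale"],
    Ki = par["K_in"], Nao = par["Na_out"], Cli = par["Cl_in"],
    Clo = par["Cl_out"], Kbath = par["K_bath"], Narest = par["Na_rest"],
    bhalf = par["boltz_half"], bslope = par["boltz_slope"],
    nuh = par["nu_half"], nus = par["nu_slope"],
    nuNth = par["nuN_threshold"], nmh = par["nmda_half"],
    nms = par["nmda_slope"];

  // schedule
  const double t_end = sch["t_end_run"], dt = sch["dt"],
    t_start_w = sch["t_start_window"], t_end_w = sch["t_end_window"],
    t_block = sch["t_block"], btau = sch["block_sigmoid_tau"],
    wtau = sch["window_sigmoid_tau"], nmda_scale = sch["nmda_scale"],
    step_amp = sch["step_amp"], step_dur = sch["step_duration"];
  const int stride = sch["record_stride"];
  NumericVector step_on = sch["step_onsets"];

  const double conv = 1e-12 / (faraday * vol * 1e-15);  // pA -> mM/ms
  const double VCl = scale * std::log(Cli / Clo);       // fixed

  // state
  double V = init[0], Vn = init[1], Gn = init[2], T = init[3],
    xs = init[4], xN = init[5], Gt = init[6], Gp = init[7],
    Ko = init[8], Nai = init[9];

  const long long nsteps = std::llround(t_end / dt);
  const long long nrec = nsteps / stride + 1;
  NumericMatrix out(nrec, 11);
  const char *fields[10] = {"V", "V_noisy", "G_noise", "T_syn", "chi_syn",
                            "chi_NMDA", "G_trans", "G_pers", "K_out", "Na_in"};

  long long irec = 0;
  out(0, 0) = 0.0; out(0, 1) = V; out(0, 2) = Vn; out(0, 3) = Gn;
  out(0, 4) = T; out(0, 5) = xs; out(0, 6) = xN; out(0, 7) = Gt;
  out(0, 8) = Gp; out(0, 9) = Ko; out(0, 10) = Nai;
  irec = 1;

  R_xlen_t ie = 0, nev = ev_time.size();
  R_xlen_t is = 0, nstep_on = step_on.size();
  double max_clamp = 0.0;

  for (long long i = 0; i < nsteps; ++i) {
    const double t = i * dt;

    // reversal potentials and pump
    const double VK = scale * std::log(Ko / Ki);
    const double VNa = scale * std::log(Nao / Nai);
    const double Ip = ipmax / ((1.0 + std::exp(pKh - Ko)) *
                               (1.0 + std::exp((pNah - Nai) / pNas)));

    // time-dependent gates
    const double fb = 1.0 - block_frac / (1.0 + std::exp((-t + t_block) / btau));
    const double W = (1.0 / (1.0 + std::exp((-t + t_start_w) / wtau))) *
      (1.0 - 1.0 / (1.0 + std::exp((-t + t_end_w) / wtau)));

    // voltage-dependent factors
    const double nu = 1.0 / (1.0 + std::exp(nus * (nuh - V)));
    const double nuN = (Vn >= nuNth) ? 1.0 : 0.0;
    const double fN = 1.0 / (1.0 + std::exp(nms * (nmh - V)));
    const double ftV = 1.0 / (1.0 + std::exp((V - bhalf) / bslope));
    const double ftVn = 1.0 / (1.0 + std::exp((Vn - bhalf) / bslope));

    // synaptic conductances
    const double Gtrig = gtrig * T * xs * fb;
    const double Grec = gGlut *
      (fampa * fb + fnmda_frac * nmda_scale * fN * xN) * xs * nu;

    // activity-dependent currents for each population
    const double itransV = gtrans * (mK * (V - VK) + mNa * (V - VNa)) *
      ftV * Gt * W;
    const double itransVn = gtrans * (mK * (Vn - VK) + mNa * (Vn - VNa)) *
      ftVn * Gt * W;
    const double ipersV = gpers * Gp * (V - VK) * W;
    const double ipersVn = gpers * Gp * (Vn - VK) * W;

    // injected current (main population only)
    double I_inj = 0.0;
    while (is < nstep_on && step_on[is] + step_dur <= t) ++is;
    if (is < nstep_on && t >= step_on[is] && t < step_on[is] + step_dur)
      I_inj = step_amp;

    // derivatives
    const double dV = -(gK * (V - VK) + gNa * (V - VNa) + gCl * (V - VCl) +
                        Ip + (Gtrig + Grec) * (V - Vglut) +
                        itransV + ipersV - I_inj) / C;
    const double dVn = -(gK * (Vn - VK) + gNa * (Vn - VNa) + gCl * (Vn - VCl) +
                         Ip + Gn * (Vn - Vglut) +
                         itransVn + ipersVn) / C;
    const double dGn = -Gn / tau_noise;
    const double dT = nuN * (1.0 - T) - T / tauT;
    const double dxs = -r_rs * nu * xs + (1.0 - xs) / tau_rs;
    const double dxN = -r_rN * nu * xN + (1.0 - xN) / tau_rN;
    const double dGt = r_trans * nu * xs * (1.0 - Gt) - Gt / tau_tr;
    const double dGp = r_pers * nu * xs * (1.0 - Gp) - Gp / tau_pers;
    const double dK = rK * nu - 2.0 * Ip * conv + (Kbath - Ko) / tauK;
    const double dNa = rNa * nu - 3.0 * Ip * conv / gamma_vol +
      (Narest - Nai) / tauNa;

    // Euler update
    V += dt * dV; Vn += dt * dVn; Gn += dt * dGn; T += dt * dT;
    xs += dt * dxs; xN += dt * dxN; Gt += dt * dGt; Gp += dt * dGp;
    Ko += dt * dK; Nai += dt * dNa;

    // Poisson shot-noise jumps landing in (t, t + dt]
    const double tnext = (i + 1) * dt;
    while (ie < nev && ev_time[ie] <= tnext + 1e-12) {
      Gn += ev_amp[ie];
      ++ie;
    }

    // clamp gate variables against round-off overshoot
    double g[5] = {T, xs, xN, Gt, Gp};
    for (int k = 0; k < 5; ++k) {
      double c = 0.0;
      if (g[k] < 0.0) { c = -g[k]; g[k] = 0.0; }
      else if (g[k] > 1.0) { c = g[k] - 1.0; g[k] = 1.0; }
      if (c > max_clamp) max_clamp = c;
    }
    T = g[0]; xs = g[1]; xN = g[2]; Gt = g[3]; Gp = g[4];

    if (!std::isfinite(V) || !std::isfinite(Vn) || !std::isfinite(Ko) ||
        !std::isfinite(Nai)) {
      double vals[10] = {V, Vn, Gn, T, xs, xN, Gt, Gp, Ko, Nai};
      for (int k = 0; k < 10; ++k)
        if (!std::isfinite(vals[k]))
          stop("integration failure: non-finite %s at t = %.3f ms",
               fields[k], tnext);
      stop("integration failure at t = %.3f ms", tnext);
    }

    if ((i + 1) % stride == 0) {
      out(irec, 0) = tnext; out(irec, 1) = V; out(irec, 2) = Vn;
      out(irec, 3) = Gn; out(irec, 4) = T; out(irec, 5) = xs;
      out(irec, 6) = xN; out(irec, 7) = Gt; out(irec, 8) = Gp;
      out(irec, 9) = Ko; out(irec, 10) = Nai;
      ++irec;
    }
    if (i % 2000000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["states"] = out,
                      _["max_clamp"] = max_clamp,
                      _["n_events_applied"] = (double)ie);
}
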