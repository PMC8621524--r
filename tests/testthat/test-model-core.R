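# Frozen expected values below were computed with an independent
# high-precision evaluation of the printed closed forms (see comments on
# each), not with the package's own functions.

test_that("Nernst potentials match high-precision evaluation and reject bad input", {
  # 26.1*log(2.5/140) and 26.1*log(151/10), evaluated independently
  expect_equal(nernst_potential(2.5, 140), -105.06167912818741,
               tolerance = 1e-12)
  expect_equal(nernst_potential(151, 10), 70.85353281372494,
               tolerance = 1e-12)
  expect_equal(nernst_potential(10, 133), -67.5406413194432,
               tolerance = 1e-12)
  expect_identical(nernst_potential(3.7, 3.7), 0)
  expect_error(nernst_potential(-1, 140), "strictly positive")
  expect_error(nernst_potential(2.5, 0), "strictly positive")
})

test_that("pump current: frozen value, saturation bound, monotonicity", {
  p <- model_parameters()
  # 23 / ((1+e^1)(1+e^5))
  expect_equal(pump_current(2.5, 10, p), 0.04139965133367706,
               tolerance = 1e-12)
  expect_equal(pump_current(1e3, 1e3, p), 23, tolerance = 1e-12)
  expect_gt(pump_current(5, 15, p), pump_current(2.5, 10, p))
  grid <- expand.grid(K = seq(1, 12, by = 0.5), Na = seq(5, 40, by = 2.5))
  v <- pump_current(grid$K, grid$Na, p)
  expect_true(all(v > 0 & v < p$Ipump_max))
})

test_that("voltage sigmoids hit midpoints and frozen values to 1e-12", {
  p <- model_parameters()
  expect_equal(f_nmda(-47.77, p), 0.5, tolerance = 1e-12)
  expect_equal(f_nmda(0, p), 0.9461500654583223, tolerance = 1e-12)
  expect_equal(f_nmda(-120, p), 0.012947762120050861, tolerance = 1e-12)
  expect_equal(nu_main(-30, p), 0.5, tolerance = 1e-12)
  expect_equal(nu_main(-40, p), 0.05416670048123607, tolerance = 1e-12)
  expect_equal(nu_main(0, p), 0.9998122102941909, tolerance = 1e-12)
  expect_equal(f_trans(-65.63, p), 0.5, tolerance = 1e-12)
  expect_equal(f_trans(-27, p), 0.01919340509123139, tolerance = 1e-12)
  expect_equal(f_trans(-100, p), 0.9706877692486436, tolerance = 1e-12)
})

test_that("noisy-population transfer is a unit step at -35 mV", {
  expect_identical(nu_noisy(c(-35, -35.0001, 0, -120)), c(1, 0, 1, 0))
})

test_that("sigmoids are bounded in (0,1) and monotone on a voltage grid", {
  p <- model_parameters()
  v <- seq(-120, 20, by = 0.25)
  for (f in list(f_nmda, nu_main)) {
    y <- f(v, p)
    expect_true(all(y > 0 & y < 1))
    expect_true(all(diff(y) > 0))
  }
  y <- f_trans(v, p)
  expect_true(all(y > 0 & y < 1))
  expect_true(all(diff(y) < 0))
})

test_that("drug-block sigmoid spans 1 to 0.7 with midpoint 0.85 at t_block", {
  s <- protocol_schedule()
  p <- model_parameters()
  expect_equal(f_block(0, s, p), 1, tolerance = 1e-12)
  expect_equal(f_block(s$t_block, s, p), 0.85, tolerance = 1e-12)
  expect_equal(f_block(s$t_block + 1e6, s, p), 0.7, tolerance = 1e-10)
  t <- seq(0, 600000, by = 1000)
  expect_true(all(diff(f_block(t, s, p)) <= 0))
})

test_that("window gate saturates inside the window and halves at its edge", {
  s <- protocol_schedule()
  expect_equal(window_gate(300000, s), 1, tolerance = 1e-4)
  expect_equal(window_gate(s$t_start_window, s), 0.5, tolerance = 1e-6)
  expect_lt(window_gate(0, s), 1e-4)
  t <- seq(0, 600000, by = 500)
  w <- window_gate(t, s)
  expect_true(all(w > 0 & w < 1))
})

test_that("transient current reverses at the weighted Nernst mixture and gates off", {
  p <- model_parameters()
  s_on <- sched_window_on()
  st <- initial_state(p)
  st$G_trans <- 1
  st$t <- 5000
  rev <- reversal_potentials(st, p)
  U_rev <- p$m_K * rev$V_K + p$m_Na * rev$V_Na
  # 0.8*(-105.0617) + 0.2*70.8535, independent evaluation
  expect_equal(U_rev, -69.87863673980493, tolerance = 1e-12)
  expect_equal(transient_current(U_rev, st, s_on, p), 0, tolerance = 1e-9)
  expect_lt(transient_current(-120, st, s_on, p), 0)  # inward below reversal
  st0 <- st; st0$G_trans <- 0
  expect_identical(transient_current(-50, st0, s_on, p), 0)
  s_off <- sched_quiet()
  expect_equal(transient_current(-50, st, s_off, p), 0, tolerance = 1e-30)
})

test_that("persistent current is ohmic in (U - V_K) and window-gated", {
  p <- model_parameters()
  s_on <- sched_window_on()
  st <- initial_state(p)
  st$G_pers <- 1
  st$t <- 5000
  V_K <- reversal_potentials(st, p)$V_K
  expect_equal(persistent_current(V_K, st, s_on, p), 0, tolerance = 1e-12)
  expect_equal(persistent_current(V_K + 10, st, s_on, p), 20,
               tolerance = 1e-12)  # g_pers = 2 nS
  expect_equal(persistent_current(V_K + 10, st, sched_quiet(), p), 0,
               tolerance = 1e-30)
})

test_that("trigger conductance scales with T_syn, resource, and block", {
  p <- model_parameters()
  s <- protocol_schedule()
  st <- initial_state(p)
  expect_identical(trigger_conductance(st, s, p), 0)  # T_syn = 0
  st$T_syn <- 1
  st$t <- 0
  expect_equal(trigger_conductance(st, s, p), 9.5, tolerance = 1e-10)
  st$t <- s$t_block + 1e6
  expect_equal(trigger_conductance(st, s, p), 9.5 * 0.7, tolerance = 1e-8)
})

test_that("reciprocal conductance: exhausted resource, hyperpolarized limit, frozen value", {
  p <- model_parameters()
  s <- protocol_schedule()
  st <- initial_state(p)
  st$chi_syn <- 0
  st$V <- -30
  expect_identical(reciprocal_conductance(st, s, p), 0)
  st$chi_syn <- 1
  st$V <- -120
  expect_lt(reciprocal_conductance(st, s, p), 1e-9)
  st$V <- -30
  st$t <- 0
  # 30*(0.33 + 0.67*f_nmda(-30))*1*nu(-30), independent evaluation
  expect_equal(reciprocal_conductance(st, s, p), 12.425929574109684,
               tolerance = 1e-10)
  expect_lte(reciprocal_conductance(st, s, p), p$g_Glut)
})

test_that("pump flux conversion matches the dimensional-analysis oracle", {
  p <- model_parameters()
  # 1 pA into 300 um^3: 1e-12 C/s / (96485 C/mol * 3e-13 L) in M/s == mM/ms
  expect_equal(pump_flux_factor(p), 3.4547684441450313e-05,
               tolerance = 1e-12)
  # 23 pA => 7.946e-4 mM/ms
  expect_equal(23 * pump_flux_factor(p), 7.945967421533572e-04,
               tolerance = 1e-12)
})

test_that("derivatives vanish at the leak/pump voltage balance and follow the ion oracle", {
  p <- model_parameters()
  s <- sched_quiet()
  # V* solving gK(V-VK)+gNa(V-VNa)+gCl(V-VCl)+Ipump = 0 at rest ions,
  # computed independently from the frozen Nernst/pump values
  vstar <- -72.86520859766999
  st <- model_state(t = 0, V = vstar, V_noisy = vstar, K_out = 2.5,
                    Na_in = 10)
  d <- model_derivatives(st, s, p)
  # V* balances leak + pump; the residual is the recurrent-drive tail at
  # nu(V*) ~ 5e-6, worth ~5e-5 mV/ms
  expect_lt(abs(d[["V"]]), 1e-4)
  expect_lt(abs(d[["V_noisy"]]), 1e-6)    # no recurrent drive on this population
  expect_identical(d[["T_syn"]], 0)       # nu_noisy(-72.9) = 0
  expect_lt(abs(d[["chi_syn"]]), 1e-7)    # nu(V*) tail on the full resource
  # dK_out at rest, nu ~ 0: -2 Ipump/(F v) = -2.861e-6 mM/ms (oracle);
  # the tiny nu(V*) * r_K term adds ~8e-9
  expect_equal(d[["K_out"]], -2.8605241805238852e-06, tolerance = 5e-3)
})

test_that("all ionic currents are inward at -120 mV (sign convention)", {
  p <- model_parameters()
  st <- initial_state(p)
  st$V <- -120
  d <- model_derivatives(st, sched_quiet(), p)
  expect_gt(d[["V"]], 0)
})

test_that("resource equations have the expected fixed points", {
  p <- model_parameters()
  s <- sched_quiet()
  # full resource with (numerically) silent population stays put
  st <- initial_state(p)
  st$V <- -120
  d <- model_derivatives(st, s, p)
  expect_lt(abs(d[["chi_syn"]]), 1e-10)
  expect_lt(abs(d[["chi_NMDA"]]), 1e-10)
  # at saturated firing the fast resource equilibrates at 1/(1 + r_rs tau_rs)
  st$V <- 50   # nu(50) = 1 - 1e-10
  st$chi_syn <- 1 / (1 + p$r_rs * p$tau_rs)   # 1/5.5
  d <- model_derivatives(st, s, p)
  expect_lt(abs(d[["chi_syn"]]), 1e-9)
})

test_that("derivatives match finite differences of closed-form linear solutions", {
  p <- model_parameters()
  s <- sched_quiet()
  h <- 1e-3
  fd <- function(x, t0) (x(t0 + h) - x(t0 - h)) / (2 * h)
  check <- function(field, closed_form, t0, make_state, tol = 1e-6) {
    st <- make_state(closed_form(t0))
    d <- model_derivatives(st, s, p)
    expect_equal(d[[field]], fd(closed_form, t0), tolerance = tol)
  }
  base <- initial_state(p)

  # noise conductance drift: G(t) = 5 exp(-t/25)
  check("G_noise", function(t) 5 * exp(-t / p$tau_noise), 7,
        function(v) { st <- base; st$G_noise <- v; st$V_noisy <- -120; st })
  # trigger transduction at nu_N = 1: a = 1 + 1/tau_T
  aT <- 1 + 1 / p$tau_T
  check("T_syn", function(t) (1 / aT) * (1 - exp(-aT * t)), 2,
        function(v) { st <- base; st$T_syn <- v; st$V_noisy <- 0; st })
  # fast resource at nu = 1/2 exactly (V = -30)
  a <- p$r_rs * 0.5 + 1 / p$tau_rs
  eq <- (1 / p$tau_rs) / a
  check("chi_syn", function(t) eq + (1 - eq) * exp(-a * t), 400,
        function(v) { st <- base; st$V <- -30; st$chi_syn <- v; st })
  # NMDA availability at nu = 1/2
  aN <- p$r_rN * 0.5 + 1 / p$tau_rN
  eqN <- (1 / p$tau_rN) / aN
  check("chi_NMDA", function(t) eqN + (1 - eqN) * exp(-aN * t), 5000,
        function(v) { st <- base; st$V <- -30; st$chi_NMDA <- v; st })
  # transient gate at nu = 1/2, frozen resource 0.7
  ag <- p$r_trans * 0.5 * 0.7 + 1 / p$tau_tr
  bg <- p$r_trans * 0.5 * 0.7
  check("G_trans", function(t) (bg / ag) * (1 - exp(-ag * t)), 300,
        function(v) { st <- base; st$V <- -30; st$chi_syn <- 0.7
                      st$G_trans <- v; st })
  # persistent gate, same structure
  ap <- p$r_pers * 0.5 * 0.7 + 1 / p$tau_pers
  bp <- p$r_pers * 0.5 * 0.7
  check("G_pers", function(t) (bp / ap) * (1 - exp(-ap * t)), 2000,
        function(v) { st <- base; st$V <- -30; st$chi_syn <- 0.7
                      st$G_pers <- v; st })
  # ion relaxation with the pump silenced (Ipump_max = 0) and nu = 1/2
  p0 <- model_parameters(Ipump_max = 0)
  aK <- 1 / p0$tau_K
  KK <- function(t) (2.5 + p0$r_K * 0.5 * p0$tau_K) +
    (2.5 - (2.5 + p0$r_K * 0.5 * p0$tau_K)) * exp(-aK * t)
  st <- base; st$V <- -30; st$K_out <- KK(1000)
  d <- model_derivatives(st, s, p0)
  expect_equal(d[["K_out"]], fd(KK, 1000), tolerance = 1e-6)
})

test_that("ion pools relax to bath/rest values when the pump is silenced", {
  p <- model_parameters(Ipump_max = 0)
  s <- sched_quiet()
  st <- initial_state(p)
  st$V <- -120; st$V_noisy <- -120   # nu essentially 0
  st$K_out <- 4; st$Na_in <- 14
  d <- model_derivatives(st, s, p)
  expect_equal(d[["K_out"]], (2.5 - 4) / p$tau_K, tolerance = 1e-6)
  expect_equal(d[["Na_in"]], (10 - 14) / p$tau_Na, tolerance = 1e-6)
})

test_that("model input conductance sums leaks and windowed activity terms", {
  p <- model_parameters()
  st <- initial_state(p)
  st$t <- 5000
  expect_equal(model_input_conductance(st, sched_window_on(), p), 3,
               tolerance = 1e-12)
  st$G_trans <- 1; st$G_pers <- 1
  expect_equal(model_input_conductance(st, sched_quiet(), p), 3,
               tolerance = 1e-9)
  st$V <- -65.63   # f_trans midpoint: 3 + 2*0.5 + 2*1
  expect_equal(model_input_conductance(st, sched_window_on(), p), 6,
               tolerance = 1e-12)
})

test_that("parameter, schedule and state constructors enforce their invariants", {
  expect_error(model_parameters(gq = 1), "unknown model parameter")
  expect_error(model_parameters(m_K = 0.5), "m_K \\+ m_Na")
  expect_error(model_parameters(block_fraction = 1.5), "block_fraction")
  expect_error(model_parameters(g_trig = -1), "non-negative")
  expect_error(protocol_schedule(dt = 0.5), "0.1 ms")
  expect_error(protocol_schedule(t_start_window = 5e5, t_end_window = 4e5),
               "t_start_window")
  expect_error(model_state(chi_syn = 1.2), "chi_syn")
  expect_error(model_state(K_out = -1), "strictly positive")
})
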