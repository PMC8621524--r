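---
title: "Model and methods notes for ecdischarge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods notes for ecdischarge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdischarge)
```

## The model and its assumptions

`ecdischarge` simulates the status-epilepticus-like regime of recurrent
discharges recorded in entorhinal cortex slices under a proepileptic
solution, and the effect of blocking the calcium-permeable AMPA-receptor
(CP-AMPAR) fraction.  It is a mean-field (population-rate) model: no
spatial structure, no spiking neurons, and no inhibitory synaptic input
(the experimental preparation contains a GABA~A~ antagonist).  Two
populations are distinguished only by their drive: the *noisy*
population receives Poisson shot-noise conductance and, when it crosses
a hard firing threshold, transiently opens a triggering glutamatergic
conductance onto the *main* population, which then recruits itself
through recurrent AMPA/NMDA input.

The state is ten-dimensional: two membrane voltages, the noise
conductance, the trigger transduction variable, two use-dependent
synaptic resources (fast overall depression `chi_syn`, slow NMDA
availability `chi_NMDA`), two activity-dependent conductance gates
(transient `G_trans`, persistent `G_pers`), and two dynamical ion
concentrations (extracellular K⁺, intracellular Na⁺).  Everything except
the two voltages is shared globally between the populations, and only
the firing rate of the main population drives the resource, gate, and
ion equations; the currents, in contrast, act on both voltages.  This
follows the printed structure of the equations, which define one global
equation per shared variable and let the population voltage enter only
through the current terms.

Three mechanisms terminate a discharge: fast synaptic-resource
depletion, the shunting effect of the activity-dependent conductances,
and the electrogenic Na⁺/K⁺ pump driven by K⁺/Na⁺ accumulation.
The persistent conductance is a pure K⁺ current; the transient one has
a mixed reversal `0.8 V_K + 0.2 V_Na` (about −70 mV at rest ions) and an
inwardly rectifying Boltzmann voltage dependence (midpoint −65.63 mV,
slope 9.82 mV) taken from the published fit of the post-discharge
current.

### Parameters that matter most

All defaults are the published values; `model_parameters()` documents
every constant with units.  The ones that shape the regime:

* `g_trig` (9.5 nS) and `g_Glut` (30 nS): trigger strength and recurrent
  gain.  The AMPA : NMDA split of the recurrent input is 0.33 : 0.67.
* `r_rs`/`tau_rs` (0.003 ms⁻¹ / 1.5 s): fast depression; its saturated
  fixed point `1/(1 + r_rs tau_rs) = 0.18` sets how much recurrent drive
  survives sustained firing.
* `r_K` (0.0017 mM/ms) and `tau_K` (7.5 s): activity-driven K⁺ release
  and clearance; K⁺ accumulation depolarizes `V_K` and prolongs early
  discharges.
* `mu_noise`, `sigma_noise`, `lambda_noise` (8 nS, 1.5 nS, 1.5 Hz):
  the shot-noise statistics.  Only mean and variance are published; the
  amplitude distribution is chosen Gaussian, truncated at zero by
  redrawing — at 5.3 sigma the truncation is immaterial, and the choice
  is the minimal-assumption one.
* `block_fraction` (0.3) with the block sigmoid (half-time 450 s, time
  scale 15 s) and the conductance window `W(t)` (edges 120 s/480 s,
  time scale 10 s): the simulated drug protocol.

### Two readings fixed by design

The printed form of the recurrent conductance is typographically
ambiguous about what multiplies what; the package implements
`g_Glut (0.33 f_block + 0.67 f_NMDA chi_NMDA) chi_syn nu(V)`, i.e. the
fast resource and the rate function multiply both receptor fractions.
The alternative (an undepressed AMPA term) would leave a ~10 nS
recurrent conductance permanently open and pin the resting voltage near
−17 mV, which contradicts the recorded resting behaviour, so the chosen
grouping is the only physically consistent one.

Likewise, the time window `W(t)` multiplies both activity-dependent
*currents* and both activity-dependent *terms* of the total input
conductance.  Gating both is what makes the conductance trace return to
the 3.0 nS leak level outside the window, as observed.

The NMDA term carries an extra factor `nmda_scale` (default 1), an
extension hook for emulating NMDAR block experiments; the default
reproduces the unmodified model.

### Units

Voltages in mV, conductances in nS, currents in pA, times in ms,
concentrations in mM.  The pump term of the ion equations converts pA to
mM/ms through `1e-12 / (F v 1e-15)` with `v` the extracellular volume in
µm³ — numerically, mol L⁻¹ s⁻¹ equals mmol L⁻¹ ms⁻¹, so no further
factor appears.  A unit test pins this against the dimensional-analysis
value (23 pA into 300 µm³ gives 7.95 × 10⁻⁴ mM/ms).

## Numerical scheme

The integrator is explicit Euler at `dt = 0.05 ms` (hard cap 0.1 ms),
written in C++ for speed; a pure-R step (`euler_step` over
`model_derivatives`) is the reference and the test suite asserts
agreement to below 1e-12 per step.  Euler is deliberate: the Poisson
shot noise enters as true delta jumps added to the noise conductance at
the end of the step containing the event, which a first-order scheme
represents exactly, and the stiffest deterministic time constant (25 ms)
is 500 steps wide.  A convergence test verifies first-order behaviour by
Richardson comparison at dt, dt/2, dt/4, and an independent
high-accuracy re-integration was used during development to confirm that
the regime statistics are not an artifact of the scheme.

Gate variables are clamped to [0, 1] after every step; the largest clamp
applied is recorded on the trace and a warning is raised if it exceeds
1e-6, which would indicate the step size is too large.  Non-finite
states abort the run naming the offending variable and time.  Derived
trace columns (reversal potentials, pump current, synaptic conductances,
activity-dependent currents, total input conductance) are *recomputed in
R from the recorded state* with the same model-core functions, so they
are bit-for-bit reproducible from the state samples.

Infinite schedule times are legal and useful: `t_block = Inf` disables
the drug, window edges at ±1e9 pin `W = 1`, and a window far beyond the
run keeps the activity-dependent conductances off.

## Analysis procedures

*Detection.*  A discharge is a maximal interval with `V >= -35 mV`
(the model's trigger threshold), after merging interludes shorter than
200 ms and discarding events shorter than 100 ms.  The experimental
literature states no detection rule; all three constants are exposed
arguments.  Events longer than 5 s are labelled seizure-like (SLE).

*Input conductance.*  `G = I_step / ΔV` from −25 pA, 250 ms steps; the
plateau is the mean over the last 50 ms of the step and the baseline the
mean over the 50 ms before onset (the averaging windows are a package
choice; the sources report only that amplitudes were averaged).

*Fits.*  Both the single-exponential decay and the rectifying I-V model
are fitted by unweighted Levenberg–Marquardt least squares
(`minpack.lm`) from five deterministic heuristic starts (plus
negated-gain starts for the I-V fit), keeping the best converged
residual sum of squares; time constants and Boltzmann slopes are bounded
positive.  Deterministic starts keep the fits reproducible without
consuming random numbers.  Parameter-recovery tests cover 50 random
ground-truth draws across both families at 0.5 % tolerance.

A caution on the decay fit at the published protocol size: with only
four sampling times (0.5–3.5 s) and 13 replicates of 0.1 nS noise, the
linearized covariance of the estimator puts a sampling standard
deviation of roughly 130 ms on the recovered time constant (and only
~0.04/0.10 nS on the two amplitudes).  Any single realization can
therefore sit well outside the published ±70 ms error bar without any
defect in the fitting; the acceptance suite accordingly asserts recovery
on the estimator's mean over 20 independent realizations, while the
acceptance script reports the single-draw value at the requested seed.

*Rectification index.*  Straight lines are fitted separately to the
points above and below the reversal potential and their slope ratio is
reported.  Which points enter each side is not specified in the
experimental sources; the all-points-per-side rule is this package's
documented choice.  Note that on the published curve sampled over the
full −107..−27 mV grid the depolarized limb is non-monotonic, so the
index can legitimately be near zero or slightly negative even though the
curve rectifies inwardly.

## The synthetic-data generators

The fixtures module exists so that every analysis operation is testable
against known ground truth without running the simulator.  It emulates
the *shape* of the experimental data — single-exponential conductance
decays, Boltzmann-rectified I-V samples, voltage traces with discharges
at a target rate (0.21 Hz, 480 ms) on a −74.7 mV baseline with implanted
step responses — but not its full statistics: sample noise is i.i.d.
Gaussian (real recordings have colored noise with no published spectral
description), discharge waveforms are rectangular with a rounded
sub-threshold after-depolarization tail, and onsets are Poisson with an
enforced refractory gap (the realized rate is `1/(refractory + 1/rate)`,
slightly below nominal).  The rectangular body is chosen so the
ground-truth onset, offset and duration coincide with the detection
threshold crossings, making detection round-trips exact to one sample;
only those three fields are contractual, the waveform itself is not.
Passing fixture tests therefore validates the analysis algebra, not the
realism of slice recordings.

## What the default simulation does (and one honest caveat)

At the published parameters the model reproduces the qualitative regime:
an initial seizure-onset epoch in the first minute with strongly
elevated extracellular K⁺ (7–8 mM for tens of seconds) and discharges an
order of magnitude longer than the later steady ones, then steady
sub-second discharges at ~0.15–0.2 Hz while the activity-dependent
conductances hold the input conductance near 4 nS, then — after the
simulated CP-AMPAR block removes 30 % of the AMPA conductance and the
activity-dependent shunt — a two- to three-fold increase in discharge
frequency with the input conductance back at the 3 nS leak level and an
overall depolarization.  These statistics are computed by the test suite
across five seeds.

The caveat: the initial seizure-like epoch manifests as a dense *cluster*
of 1–3 s discharges separated by sub-threshold interludes of a few
hundred ms to a few seconds, not as one continuous supra-threshold
plateau.  Under the default detection rule no single event exceeds 5 s,
so the SLE *label* is never assigned even though the slow K⁺ envelope of
the epoch is present.  This is a property of the equations, not of the
integrator: a high-accuracy adaptive re-integration of the same noise
realization reproduces it, and quasi-static analysis shows why — the
sustained-depolarization fixed point requires extracellular K⁺ above
roughly 7 mM, and the fast synaptic resource (depletion time ~0.3 s at
full drive) collapses each discharge before K⁺ can accumulate that far,
producing relaxation-oscillation bursting instead of a plateau.  The
corresponding acceptance expectation is left failing rather than
redefining the event rule post hoc.

## Problem sizes and runtimes

Chosen for tight, informative tests: full 600-s runs at 0.05 ms steps
(a few seconds each, compiled) are used in the regime checks over five
seeds; shorter 100–300 s runs serve the stationarity, ion-baseline and
Campbell-theorem checks; fits and fixtures are effectively instant.
The whole suite runs in well under a minute on one core.

## Known limitations

* No GABA~A~/GABA~B~ currents, no Cl⁻ dynamics (fixed concentrations),
  no spatial propagation, no spike-level detail.
* The drug is a conductance scaling, not receptor pharmacology; NMDAR
  block is available only through the `nmda_scale` hook.
* The discharge-frequency match to experiment is qualitative; no animal
  statistics are modelled.
* Euler at fixed step: adequate here (verified first-order convergent,
  clamp-monitored), but there is no adaptive error control.
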