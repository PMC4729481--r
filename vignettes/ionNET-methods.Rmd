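---
title: "ionNET: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ionNET: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open.

## The model

`ionNET` treats the yeast plasma membrane as a near-equilibrium
thermodynamic system. The state comprises the internal and external
concentrations of H+, K+, Na+ and Cl- (mM, with mM ≡ mol m^-3 exploited
throughout), the membrane potential Δφ = φ_in − φ_out (V), the ATP
concentration (mM), and the live values of the four glucose-modifiable
phenomenological coefficients.

Fluxes are outward-positive and linear in the generalized forces,

    J_i  = Σ_j L_ij X_j ,
    X_i  = R ln(c_i^in / c_i^out) + z_i F Δφ / T      (ions)
    X_Ar = (R / c̄_ATP) (c_ATP − c̄_ATP) (1 + K)        (ATP hydrolysis)

with a symmetric coefficient matrix over the index set {H, K, Na, Cl, Ar}.
The standard chemical potentials cancel in the in/out difference, so they
never appear. Reciprocity is structural: only one triangle of `L` is
stored. Straight coefficients are constrained non-negative; cross
coefficients may take either sign. `L_NaAr`, `L_ClAr` and `L_ArAr` are
identically zero (no sodium-ATP coupling under the modelled conditions;
the reaction's own straight coefficient is not part of the published
model). With an active ATP cross-coupling and `L_ArAr = 0`, the full 5×5
matrix necessarily has a negative eigenvalue; `validate_onsager()`
therefore treats positive-semidefiniteness and the determinant condition
as warning-level diagnostics while symmetry and diagonal non-negativity
remain hard.

The balance laws are surface-to-volume scalings of the fluxes. The
internal proton balance is divided by a buffering factor

    Bf = pbc / (ln 10 · c_H^in(0)),

the standard conversion of a buffer capacity (`pbc`, mM per pH unit) into
the ratio of total to free proton change, evaluated once at the initial
state and then held constant. A pH-dependent mode that recomputes `Bf`
each step is available in the reference R engine
(`simulate_fluxes(..., engine = "R", buffering = "dynamic")`); with the
shipped parameter sets the internal pH moves little and the two modes
agree closely. ATP obeys `dATP/dt = k_ATPincr − k_ATPdecr·ATP` with
`k_ATPdecr := k_ATPincr / ATP_stimulus`, so the post-glucose fixed point
is `ATP_stimulus` (2.5 mM in all shipped sets). Before the glucose event
both constants are zero: starved cells hold their estimated initial ATP
frozen, because the published protocol defines the decay constant only
through the post-stimulus relation. Each glucose-modifiable coefficient
relaxes as `dL/dt = k_incr − k_decr·L`, `k_decr := k_incr / L_aG`, an
exponential approach to its post-glucose asymptote. The membrane
potential evolves capacitively,

    dΔφ/dt = −(2 F / C_m) (J_H + J_K + J_Na − J_Cl),

implemented literally as printed in the source model, including the
factor 2 whose physical origin the source does not explain; since Δφ
relaxes to the zero-net-charge-flux manifold within milliseconds, the
factor affects the relaxation speed but not the quasi-steady potential,
which is what every reported quantity depends on.

### Assumptions and known limitations

* Near-equilibrium linearity: forces large enough to leave the linear
  regime are not modelled.
* Homogeneous, constant-volume compartments; no osmotic/turgor coupling,
  no organellar transport, no transcriptional regulation.
* Glucose is a switch, not a metabolic model.
* The printed coefficient magnitudes of the published fits carry a unit
  ambiguity (values spanning 10^-8 to 10^-1 across equally good fits), so
  absolute flux magnitudes are not a validation surface; ratio- and
  sign-based observables are.
* The published P2a set balances the pre-glucose proton flux by
  near-cancellation of large terms; modest perturbations of single
  coefficients can drain the (small) free internal proton pool within
  seconds. This is real model behaviour, handled in estimation by a
  finite penalty rather than by clamping.

## Geometry and global quantities

`cell_geometry()` builds the experimental system: `n_cells` = 3.6e5 cells
(consistent with the published monolayer: 1.2e7 cells/ml in a 3 ml bath at
the monolayer dilution), per-cell surface 63.6 um^2 (sphere of diameter
4.5 um) and volume 50 fL, giving `Surf` = 2.29e-5 m^2 and
`V_in` = 1.8e-11 m^3; `V_out` = 2.85e-6 m^3; T = 296 K. The specific
membrane capacitance `C_m` is not tabulated in the source; the default
0.01 F m^-2 is the textbook 1 uF cm^-2 class of values and is exposed as
an argument (`parameter_set(name, Cm = ...)`). pH↔mM conversion uses the
mM/M factor `cf` = 1000 (pH 5.5 → 3.162e-3 mM).

## Scenarios and numerics

Stimuli are instantaneous events: a KCl addition steps external K+ and
Cl- up equimolarly (bath dilution neglected — doses are treated as bath
concentrations); glucose switches energization on. Four canonical
protocols are shipped (`canonical_scenarios()`): KCl 300 s / glucose
600 s (the fitting protocol), 300 s / 660 s (the simulation-figure
protocol, default for decomposition readouts — the source itself uses
both times), 180 s / 300 s (chloride validation), and the second-stimulus
protocol with an extra 10 mM KCl at 1000 s.

Integration is piecewise LSODA between events with exact restarts at
event times; trajectory rows at event times report the post-event state.
Default tolerances are rtol 1e-8 / atol 1e-10 (estimation uses 1e-6/1e-8
for speed; the grid-refinement and engine-equivalence tests bound the
difference). The right-hand side exists twice: a compiled C version used
by default and a pure-R reference (`model_rhs()`); their trajectories are
compared in the test suite. Inside the integrator the logarithm is
extended linearly below 1e-15 mM so that stiff-solver trial steps that
undershoot zero stay finite and can be rejected; accepted states are
positivity-checked afterwards and a non-positive concentration raises a
domain error — there is no concentration floor or clamping. A step cap
(`maxsteps`, default 10^4 per output interval) makes runaway integrations
at pathological parameter combinations fail fast; in the estimation
objective such failures return the finite penalty
`1e6 · (1 + unfinished horizon fraction)` so a particle swarm can
continue past them.

## Estimation

`fit_problem()` couples a flux dataset (conditions share one parameter
vector; only the KCl dose differs), the free parameters with bound
envelopes, the protocol and the weighting. The default weighting divides
each (condition, ion) trace's squared residuals by the trace's mean
squared flux so that K+ and H+ traces of different magnitude contribute
comparably; unweighted SSE is available (`weighting = "none"`). The exact
weighting used in the original COPASI fits is not documented; both modes
are therefore explicit options.

`pso()` is a standard global-best particle swarm: inertia 0.729,
cognitive = social = 1.49445 (the usual constriction-equivalent values;
the source states only swarm size 40, iteration limit 400 and a 1e-6
stall criterion), velocity clamped to half the bound width, positions
clamped to the bounds, termination on the iteration limit or when the
standard deviation of the personal-best objectives falls below
`stall_sd`. Dimensions with strictly positive bounds are searched in
log10 space because the coefficients span decades. Runs are deterministic
given a seed (Mersenne-Twister, R's default).

`fit_fluxes()` is the multistart protocol: run 1 uses the full envelope,
subsequent runs draw randomized start positions and randomized bounds
inside the envelope (log-uniformly for positive parameters, uniformly
otherwise — the source says only "random upper and lower parameter
bounds"). If the winning parameter sits on an envelope bound, that bound
is extended a hundredfold and one follow-up estimation is run (at most
two rounds). The published protocol used 1000 restarts; the package
default is `n_starts = 50`, and the full protocol is one argument away.

### Estimator benchmark

The parameter-recovery benchmark deliberately does not use the published
P2a set as ground truth: its knife-edge proton balance (see above) makes
half of each coefficient axis infeasible, which tests the penalty
machinery rather than the estimator. Instead the benchmark truth is a
reduced, well-conditioned M2 configuration defined in the test helpers
(strong proton buffering `pbc` = 20000 mM/pH, no H+/Cl- coupling,
moderate coefficient magnitudes, labelled synthetic). Three coefficients
(`L_KK`, `L_ClCl`, `L_HHinit`) are recovered from noiseless and from 5 %
relative-noise data over two KCl doses (0.1 and 10 mM) with K+, H+ and
Cl- traces sampled every 20 s — the chloride trace is included because
`L_ClCl` is only weakly identified by the cation traces. Problem sizes
(20 restarts, swarm 10, 30 iterations, ~60 samples per trace) are the
package's chosen benchmark scale; the acceptance thresholds are 10 %
relative error per parameter on noiseless data and 30 % under noise.

## Synthetic data

`synthesize_fluxes()` samples simulated net fluxes (nmol m^-2 s^-1,
outward positive) on a regular grid — default cadence 5 s, a typical
microelectrode acquisition rate — and adds Gaussian noise with
sd = `relative_sd`·|J| + `floor_sd` (defaults 0.05 and 2 nmol m^-2 s^-1,
chosen to resemble published flux-trace scatter; they are synthetic
choices, not values fitted to any dataset). The generator emulates the
shape of the deposited measurement series (per-condition, per-ion net
flux over ~0–1200 s with KCl and glucose events) but none of the
electrode physics: no drift, no autocorrelated noise, no convective
artefacts, and sign conventions are explicit metadata rather than a
guess. Passing tests on such data demonstrates correctness of the
estimator and analysis chain, not robustness to real-electrode artefacts.
The CSV dialect (`write_flux_csv()`/`read_flux_csv()`) carries the sign
convention in its metadata and converts influx-positive files to the
model's outward-positive convention on load.

## Decompositions and readouts

For models whose K+ flux couples only to H+ (the M2 class — anything
else is rejected by name), the K+ net flux splits exactly either by ion,
`J_K = L_KH X_H + L_KK X_K`, or by potential type,

    J_K(CP) = R (L_KH ln(c_H ratio) + L_KK ln(c_K ratio)),
    J_K(EP) = (L_KH + L_KK) F Δφ / T .

The ratio `J_K(EP)/J_K(CP)` is reported where the denominator is nonzero
and `NA` elsewhere. The "directly after glucose" readout
(`potential_ratio()`) is operationalized as the first output grid point
at least 5 s past the glucose event on a 1 s grid; the delay is an
argument (`t_after`). The readout instant behind the printed reference
value (≈3.5) is not stated in the source; with the shipped P2a set the
computed ratio decays from ≈4.8 just after glucose through 3.5 at ≈35 s
to ≈3.0 at one minute, so the +5 s default reads ≈4.7; users probing the
published value should set `t_after` explicitly.

`second_stimulus_response()` summarizes each run by the post-glucose peak
|J| per ion, the response magnitude to the second KCl addition (peak
deviation of the flux from its value just before the event, within a
150 s window), and a transient-H+-influx flag defined as a sign change of
the outward-positive `J_H` shortly after the addition. With the shipped
P2a set the sign flip occurs at all four first doses, not only at the two
highest as the source reports; the corresponding acceptance check asserts
the source's claim and is expected to flag this divergence.

`local_sensitivity()` computes central-difference relative sensitivities
`(p/f) df/dp`, stepping symmetrically in log space for strictly positive
parameters (accuracy O(rel_step^2); the step-halving test bounds the
truncation error); non-finite observables at a perturbed point flag the
entry instead of propagating.

## Configuration files

Parameter sets are flat YAML files whose coefficient keys follow the
published table names exactly (`L_HHinit`, `L_HHaG`, `k_incrHAr`, ...);
units are documented in file comments. Values written without a decimal
point in scientific notation (`3e-7`) are coerced numerically on load.
Validation reports missing sections, unknown or duplicated keys (e.g.
`L_KK` given both statically and dynamically), negative straight
coefficients, and non-positive concentrations, and computes the derived
quantities (`k_decr` per dynamic coefficient, `k_ATPdecr`, `Bf`) so their
defining identities hold exactly.
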