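# Model core: electrochemical forces, phenomenological fluxes, and the
# time derivatives of concentrations, ATP, membrane potential and the
# glucose-modifiable coefficients.
#
# State vector ordering (used throughout the package, R and C engines):
#   1 H_in  2 K_in  3 Na_in  4 Cl_in      internal concentrations, mM
#   5 H_out 6 K_out 7 Na_out 8 Cl_out     external concentrations, mM
#   9 dphi                                 membrane potential, V (in - out)
#  10 ATP                                  mM
#  11 L_HH 12 L_KK 13 L_HAr 14 L_KAr      live coefficient values

.state_names <- c("H_in", "K_in", "Na_in", "Cl_in",
                  "H_out", "K_out", "Na_out", "Cl_out",
                  "dphi", "ATP", "L_HH", "L_KK", "L_HAr", "L_KAr")

.ion_charge <- c(H = 1, K = 1, Na = 1, Cl = -1)

# log with a linear extension below .cmin, mirroring the compiled rhs: keeps
# the derivative finite when a stiff-solver trial step undershoots zero
# (reported states are positivity-checked after integration).
.cmin <- 1e-15
safe_log <- function(x) ifelse(x > .cmin, log(pmax(x, .cmin)),
                               log(.cmin) + (x - .cmin) / .cmin)

#' Electrochemical driving force of an ion
#'
#' The per-temperature force conjugate to an outward-positive ion flux:
#' `R*ln(c_in/c_out) + z*F*dphi/T` (J mol-1 K-1). The standard chemical
#' potential cancels in the in/out difference. The force vanishes at the
#' Nernst equilibrium `dphi = -(R*T)/(z*F) * ln(c_in/c_out)`.
#'
#' @param ion one of `"H"`, `"K"`, `"Na"`, `"Cl"` (charge +1, +1, +1, -1).
#' @param c_in,c_out concentrations, mM (strictly positive).
#' @param dphi membrane potential, V (inside minus outside).
#' @param geom an [cell_geometry()] object (temperature and constants).
#' @return Force in J mol-1 K-1.
#' @export
electrochemical_force <- function(ion, c_in, c_out, dphi, geom = cell_geometry()) {
  ion <- match.arg(ion, names(.ion_charge))
  if (any(c_in <= 0) || any(c_out <= 0))
    stop("non-positive concentration for ion ", ion)
  geom$R * log(c_in / c_out) + .ion_charge[[ion]] * geom$F * dphi / geom$T
}

#' Affinity of the ATP hydrolysis reaction
#'
#' `A_Ar = (R*T/C_ATP) * (c_ATP - C_ATP) * (1 + K)` where `C_ATP` is the
#' equilibrium ATP concentration and `K` the reaction equilibrium constant.
#' Positive when ATP is above its equilibrium concentration, i.e. when
#' hydrolysis can drive active transport.
#'
#' @param atp list with `C_ATP` (mM) and `K` (see [ion_params()]).
#' @param c_ATP current ATP concentration, mM.
#' @param geom an [cell_geometry()] object.
#' @return Affinity in J mol-1.
#' @export
atp_affinity <- function(atp, c_ATP, geom = cell_geometry()) {
  if (is.null(atp$C_ATP) || atp$C_ATP <= 0)
    stop("equilibrium ATP concentration C_ATP must be > 0")
  (geom$R * geom$T / atp$C_ATP) * (c_ATP - atp$C_ATP) * (1 + atp$K)
}

#' Force vector at a system state
#'
#' Unlike [electrochemical_force()], which raises a domain error on
#' non-positive concentrations, this integrator-facing variant extends the
#' logarithm linearly below a tiny floor so stiff-solver trial steps stay
#' finite; accepted trajectory states are positivity-checked separately.
#'
#' @param state named numeric state vector (see package state ordering) or a
#'   list with the same names.
#' @param params an `ion_params` object.
#' @return Named numeric `c(H, K, Na, Cl, Ar)`, J mol-1 K-1 (the reaction
#'   entry is `A_Ar / T`).
#' @export
force_vector <- function(state, params) {
  g <- params$geometry
  s <- as.list(state)
  f <- vapply(c("H", "K", "Na", "Cl"), function(ion) {
    g$R * (safe_log(s[[paste0(ion, "_in")]]) -
             safe_log(s[[paste0(ion, "_out")]])) +
      .ion_charge[[ion]] * g$F * s$dphi / g$T
  }, numeric(1))
  c(f, Ar = atp_affinity(params$atp, s$ATP, g) / g$T)
}

#' Phenomenological fluxes at a system state
#'
#' Linear force-flux law `J = L X` with the 5x5 symmetric coefficient matrix
#' over (H, K, Na, Cl, Ar), evaluated with the live values of the
#' glucose-modifiable coefficients carried in the state. Ion fluxes are
#' outward-positive, mol m-2 s-1; the `Ar` entry is the diagnostic reaction
#' rate from the same linear law (ATP itself evolves by first-order
#' production/consumption kinetics, not by this row).
#'
#' @inheritParams force_vector
#' @return Named numeric `c(H, K, Na, Cl, Ar)`.
#' @export
ion_fluxes <- function(state, params) {
  s <- as.list(state)
  L <- coefficient_matrix(params, live = c(HH = s$L_HH, KK = s$L_KK,
                                           HAr = s$L_HAr, KAr = s$L_KAr))
  X <- force_vector(state, params)
  drop(L %*% X)
}

#' Concentration derivatives implied by a flux vector
#'
#' Surface-to-volume scaling of the outward-positive fluxes:
#' `dc_out/dt = J*Surf/V_out`, `dc_in/dt = -J*Surf/V_in` (mM s-1; a flux in
#' mol m-2 s-1 times m2/m3 is mol m-3 s-1 = mM s-1). The internal proton
#' pool is buffered: its divisor is `V_in * Bf`.
#'
#' @param fluxes named numeric with at least `H`, `K`, `Na`, `Cl`.
#' @param geom an [cell_geometry()] object.
#' @param Bf dimensionless proton buffering factor (>= 1 in practice).
#' @return Named numeric of the 8 concentration derivatives, mM s-1, in
#'   state ordering.
#' @export
concentration_derivatives <- function(fluxes, geom, Bf = 1) {
  J <- fluxes[c("H", "K", "Na", "Cl")]
  a_in <- geom$Surf / geom$V_in
  a_out <- geom$Surf / geom$V_out
  d_in <- -J * a_in
  d_in[["H"]] <- d_in[["H"]] / Bf
  d_out <- J * a_out
  stats::setNames(c(d_in, d_out),
                  c("H_in", "K_in", "Na_in", "Cl_in",
                    "H_out", "K_out", "Na_out", "Cl_out"))
}

#' ATP concentration derivative
#'
#' First-order production/consumption `dATP/dt = k_ATPincr - k_ATPdecr*ATP`
#' with `k_ATPdecr = k_ATPincr / ATP_stimulus`, so the post-glucose fixed
#' point is `ATP_stimulus`. Before the glucose event both constants are 0
#' (starved cells; ATP frozen at its initial value).
#'
#' @param atp ATP parameter list (see [ion_params()]).
#' @param c_ATP current ATP concentration, mM.
#' @param glucose_on logical; has the glucose event occurred?
#' @return dATP/dt, mM s-1.
#' @export
atp_derivative <- function(atp, c_ATP, glucose_on = TRUE) {
  if (!glucose_on) return(0)
  atp$k_ATPincr - atp$k_ATPdecr * c_ATP
}

#' Relaxation derivative of a glucose-modifiable coefficient
#'
#' `dL/dt = k_incr - k_decr*L` with `k_decr = k_incr / aG`, giving
#' exponential relaxation from the pre-glucose value towards the asymptote
#' `aG`. Inactive (pre-glucose, or static with `k_incr = 0`) coefficients
#' have zero derivative.
#'
#' @param coef one element of `ion_params$dynamic` (fields `k_incr`,
#'   `k_decr`).
#' @param value current coefficient value.
#' @param active logical; has the glucose event occurred?
#' @return dL/dt, mol^2/(J m^2 s^2).
#' @export
coefficient_derivative <- function(coef, value, active = TRUE) {
  if (!active || coef$k_incr == 0) return(0)
  coef$k_incr - coef$k_decr * value
}

#' Membrane potential derivative
#'
#' Capacitive charging by the net charge flux:
#' `d(dphi)/dt = -(2*F/Cm) * (J_H + J_K + J_Na - J_Cl)`. A net outward
#' cation flux discharges the interior and drives the potential negative.
#'
#' @param fluxes named numeric with `H`, `K`, `Na`, `Cl` (mol m-2 s-1).
#' @param geom an [cell_geometry()] object.
#' @return V s-1.
#' @export
membrane_potential_derivative <- function(fluxes, geom) {
  -(2 * geom$F / geom$Cm) *
    (fluxes[["H"]] + fluxes[["K"]] + fluxes[["Na"]] - fluxes[["Cl"]])
}

#' Full model right-hand side (reference R implementation)
#'
#' Pure function of `(t, state, params)` assembling all derivatives in the
#' package state ordering. Used directly by the R integration engine and as
#' the reference against which the compiled C right-hand side is tested.
#'
#' @param t time, s (the system is autonomous; `t` is accepted for the
#'   integrator interface).
#' @param state named numeric state vector (see package state ordering).
#' @param params an `ion_params` object.
#' @param glucose_on logical; has the glucose event occurred?
#' @param buffering `"constant"` uses the precomputed `params$Bf`;
#'   `"dynamic"` recomputes the buffering factor from the current internal
#'   proton concentration at every evaluation.
#' @return List (deSolve convention): derivative vector, then the named
#'   fluxes `J_*`, forces `X_*`, and the entropy-production density `sigma`
#'   (`sum(J*X)`, W m-2 K-1 up to the per-temperature convention).
#' @export
model_rhs <- function(t, state, params, glucose_on = FALSE,
                      buffering = c("constant", "dynamic")) {
  buffering <- match.arg(buffering)
  g <- params$geometry
  J <- ion_fluxes(state, params)
  X <- force_vector(state, params)
  Bf <- if (buffering == "constant") params$Bf
        else buffering_factor(g$pbc, state[["H_in"]])
  dconc <- concentration_derivatives(J, g, Bf)
  ddphi <- membrane_potential_derivative(J, g)
  datp <- atp_derivative(params$atp, state[["ATP"]], glucose_on)
  dL <- vapply(c("HH", "KK", "HAr", "KAr"), function(nm) {
    coefficient_derivative(params$dynamic[[nm]],
                           state[[paste0("L_", nm)]], glucose_on)
  }, numeric(1))
  deriv <- c(dconc, dphi = ddphi, ATP = datp,
             stats::setNames(dL, paste0("L_", names(dL))))
  list(unname(deriv[.state_names]),
       J_H = J[["H"]], J_K = J[["K"]], J_Na = J[["Na"]], J_Cl = J[["Cl"]],
       J_Ar = J[["Ar"]],
       X_H = X[["H"]], X_K = X[["K"]], X_Na = X[["Na"]], X_Cl = X[["Cl"]],
       X_Ar = X[["Ar"]],
       sigma = sum(J * X))
}

#' Initial state vector of a parameter set
#'
#' @param params an `ion_params` object.
#' @return Named numeric vector in the package state ordering.
#' @export
initial_state <- function(params) {
  ic <- params$init
  d <- params$dynamic
  stats::setNames(
    c(ic$H_in, ic$K_in, ic$Na_in, ic$Cl_in,
      ic$H_out, ic$K_out, ic$Na_out, ic$Cl_out,
      ic$delta_phi, params$atp$ATP0,
      d$HH$init, d$KK$init, d$HAr$init, d$KAr$init),
    .state_names)
}

# parms vector handed to the compiled rhs (layout mirrored in src/ionnet.c)
as_parms_vector <- function(params, glucose_on = FALSE) {
  g <- params$geometry; s <- params$L; d <- params$dynamic; a <- params$atp
  c(Surf = g$Surf, V_in = g$V_in, V_out = g$V_out, T = g$T, Cm = g$Cm,
    Bf = params$Bf, R = g$R, F = g$F,
    L_HK = s$HK, L_HNa = s$HNa, L_HCl = s$HCl,
    L_KNa = s$KNa, L_KCl = s$KCl, L_NaCl = s$NaCl,
    L_NaNa = s$NaNa, L_ClCl = s$ClCl,
    k_incrHH = d$HH$k_incr, k_decrHH = d$HH$k_decr,
    k_incrKK = d$KK$k_incr, k_decrKK = d$KK$k_decr,
    k_incrHAr = d$HAr$k_incr, k_decrHAr = d$HAr$k_decr,
    k_incrKAr = d$KAr$k_incr, k_decrKAr = d$KAr$k_decr,
    C_ATP = a$C_ATP, Keq = a$K, k_ATPincr = a$k_ATPincr,
    k_ATPdecr = a$k_ATPdecr,
    glucose_on = as.numeric(glucose_on))
}

#' Entropy production density along a trajectory
#'
#' `sigma = sum_i J_i X_i` over the four ion fluxes and the reaction, in the
#' model's per-temperature force convention. For a positive-semidefinite
#' coefficient matrix this is non-negative at every state (second law).
#'
#' @param traj an `ion_trajectory` (see [simulate_fluxes()]).
#' @return Numeric vector, one value per output time.
#' @export
entropy_production <- function(traj) {
  stopifnot(inherits(traj, "ion_trajectory"))
  traj$sigma
}
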