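# Post-hoc analyses of trajectories: decompositions of the K+ net flux,
# anion/sodium flux prediction, second-stimulus responses, and local
# finite-difference sensitivities.

# Couplings to K+ beyond H+ invalidate the two-term decompositions.
check_m2_class <- function(params) {
  if (params$L$KNa != 0) stop("decomposition requires L_KNa = 0")
  if (params$L$KCl != 0) stop("decomposition requires L_KCl = 0")
  d <- params$dynamic$KAr
  if (d$init != 0 || d$k_incr != 0)
    stop("decomposition requires L_KAr = 0 (use a variant M2 model)")
  invisible(TRUE)
}

#' Decompose the potassium net flux
#'
#' Splits `J_K` either by contributing ion or by potential type, for models
#' in which K+ couples only to H+ (the M2 class):
#' \describe{
#'   \item{`by = "ion"`}{`J_K(H) = L_KH * X_H` (the H+-dependent part) and
#'     `J_K(K) = L_KK * X_K` (the K+-dependent part).}
#'   \item{`by = "potential"`}{`J_K(CP) = R*(L_KH*ln(cH_in/cH_out) +
#'     L_KK*ln(cK_in/cK_out))` (chemical) and
#'     `J_K(EP) = (L_KH + L_KK)*F*dphi/T` (electrical); the ratio
#'     `J_K(EP)/J_K(CP)` is reported where the denominator is nonzero and
#'     `NA` elsewhere.}
#' }
#' Both decompositions satisfy `J_K = component1 + component2` exactly at
#' every grid point.
#'
#' @param traj an `ion_trajectory`.
#' @param by `"ion"` or `"potential"`.
#' @return A data frame of class `flux_decomposition` with `time`, the two
#'   components, `net` (their sum), and for `by = "potential"` the `ratio`
#'   column.
#' @export
decompose_flux <- function(traj, by = c("ion", "potential")) {
  by <- match.arg(by)
  stopifnot(inherits(traj, "ion_trajectory"))
  params <- attr(traj, "params")
  check_m2_class(params)
  L_KH <- params$L$HK
  L_KK <- traj$L_KK
  g <- params$geometry
  if (by == "ion") {
    comp1 <- L_KH * traj$X_H
    comp2 <- L_KK * traj$X_K
    out <- data.frame(time = traj$time, J_K_H = comp1, J_K_K = comp2,
                      net = comp1 + comp2)
  } else {
    cp <- g$R * (L_KH * log(traj$H_in / traj$H_out) +
                 L_KK * log(traj$K_in / traj$K_out))
    ep <- (L_KH + L_KK) * g$F * traj$dphi / g$T
    ratio <- ifelse(cp != 0, ep / cp, NA_real_)
    out <- data.frame(time = traj$time, J_K_CP = cp, J_K_EP = ep,
                      net = cp + ep, ratio = ratio)
  }
  structure(out, by = by, events = attr(traj, "events"),
            class = c("flux_decomposition", "data.frame"))
}

#' Electrical-to-chemical drive ratio of the K+ flux after glucose
#'
#' Readout of `|J_K(EP) / J_K(CP)|` "directly after" the glucose event,
#' operationalized as the first output grid point at least `t_after`
#' seconds past the glucose event (the ratio varies slowly on that scale).
#'
#' @param traj an `ion_trajectory` whose schedule contains a glucose event.
#' @param t_after readout delay after the glucose event, s.
#' @return Scalar ratio magnitude.
#' @export
potential_ratio <- function(traj, t_after = 5) {
  ev <- attr(traj, "events")
  t_gluc <- ev$time[ev$kind == "glucose"]
  if (length(t_gluc) != 1) stop("trajectory needs exactly one glucose event")
  dec <- decompose_flux(traj, by = "potential")
  i <- which(dec$time >= t_gluc + t_after)[1]
  if (is.na(i)) stop("trajectory ends before the readout time")
  abs(dec$J_K_EP[i] / dec$J_K_CP[i])
}

#' Predicted chloride and sodium fluxes across the KCl doses
#'
#' Runs (or accepts) one trajectory per KCl dose and summarizes the model's
#' anion/sodium predictions: the peak Cl- influx magnitude per dose (with
#' the dose at which it is maximal) and whether the Na+ flux is negligible
#' relative to the K+ flux.
#'
#' @param params an `ion_params` object (used when `trajectories` is NULL).
#' @param doses KCl doses, mM.
#' @param scenario canonical scenario name used for the simulations.
#' @param trajectories optional named list of precomputed trajectories
#'   (names `"KCl_<dose>mM"`).
#' @param na_threshold Na+ negligibility threshold as a fraction of the
#'   peak |J_K|.
#' @param step output grid step of the simulations, s.
#' @param ... passed to [simulate_fluxes()].
#' @return List with `summary` (data frame per dose: peak Cl- influx,
#'   max |J_Na|, max |J_K|, Na-negligible flag), `cl_peak_dose` (dose of
#'   maximal Cl- influx), and `na_negligible` (overall flag).
#' @export
predict_anion_and_sodium <- function(params = parameter_set("P2a"),
                                     doses = c(0.01, 0.1, 1, 10),
                                     scenario = "fig3",
                                     trajectories = NULL,
                                     na_threshold = 0.01, step = 1, ...) {
  if (is.null(trajectories)) {
    trajectories <- lapply(doses, function(d)
      simulate_fluxes(params, canonical_scenarios(d, step = step)[[scenario]],
                      ...))
    names(trajectories) <- sprintf("KCl_%gmM", doses)
  }
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    data.frame(condition = names(trajectories)[i],
               dose = doses[i],
               peak_cl_influx = max(pmax(-tr$J_Cl, 0)) * 1e9,
               max_abs_na = max(abs(tr$J_Na)) * 1e9,
               max_abs_k = max(abs(tr$J_K)) * 1e9)
  })
  summary <- do.call(rbind, rows)
  summary$na_negligible <- summary$max_abs_na <
    na_threshold * summary$max_abs_k
  list(summary = summary,
       cl_peak_dose = summary$dose[which.max(summary$peak_cl_influx)],
       na_negligible = all(summary$na_negligible),
       trajectories = trajectories)
}

#' Response to a second KCl stimulus
#'
#' Simulates the second-stimulus protocol (first KCl dose at 300 s, glucose
#' at 660 s, a second dose at 1000 s) for each first dose, and summarizes
#' per run: the post-glucose peak |J| per ion, the post-second-stimulus
#' response magnitude per ion (peak deviation of the flux from its value
#' just before the second stimulus, within `window` seconds), and whether a
#' transient H+ influx (sign change of the outward-positive `J_H`) occurs
#' shortly after the second addition.
#'
#' @param params an `ion_params` object.
#' @param first_doses first KCl doses, mM.
#' @param second_dose second KCl dose, mM.
#' @param window response window after the second stimulus, s.
#' @param step output grid step of the simulations, s.
#' @param ... passed to [simulate_fluxes()].
#' @return List with `summary` (one row per first dose) and the
#'   `trajectories`.
#' @export
second_stimulus_response <- function(params = parameter_set("P2a"),
                                     first_doses = c(0.01, 0.1, 1, 10),
                                     second_dose = 10, window = 150,
                                     step = 1, ...) {
  runs <- lapply(first_doses, function(d) {
    sched <- canonical_scenarios(d, step = step,
                                 second_dose = second_dose)$second_stimulus
    simulate_fluxes(params, sched, ...)
  })
  names(runs) <- sprintf("KCl_%gmM", first_doses)
  t2 <- 1000
  rows <- lapply(seq_along(runs), function(i) {
    tr <- runs[[i]]
    gl <- tr$time >= 660 & tr$time < t2
    post <- tr$time > t2 & tr$time <= t2 + window
    before <- max(which(tr$time <= t2))   # post-event row at t2 excluded below
    pre_idx <- max(which(tr$time < t2))
    j_h_pre <- tr$J_H[pre_idx]
    data.frame(
      condition = names(runs)[i],
      first_dose = first_doses[i],
      post_glucose_peak_JK = max(abs(tr$J_K[gl])) * 1e9,
      post_glucose_peak_JH = max(abs(tr$J_H[gl])) * 1e9,
      second_response_JK = max(abs(tr$J_K[post] - tr$J_K[pre_idx])) * 1e9,
      second_response_JH = max(abs(tr$J_H[post] - j_h_pre)) * 1e9,
      h_influx_transient = j_h_pre > 0 & any(tr$J_H[post] < 0))
  })
  list(summary = do.call(rbind, rows), trajectories = runs)
}

#' Local finite-difference parameter sensitivities
#'
#' Central-difference relative sensitivities `(p/f) df/dp` of a scalar
#' observable with respect to model parameters. Strictly positive
#' parameters are perturbed symmetrically in log space
#' (`p * exp(+-rel_step)`), others linearly (`p * (1 +- rel_step)`, or an
#' absolute step `rel_step` for zero-valued parameters, for which the
#' semi-relative sensitivity `df/dp / f` is reported).
#'
#' @param params an `ion_params` object.
#' @param observable function `ion_params -> scalar` (e.g. peak |J_K| of a
#'   scenario simulation).
#' @param param_names character vector of keys understood by
#'   [update_params()].
#' @param rel_step relative step size.
#' @return Data frame `parameter`, `value`, `sensitivity`, `ok` (FALSE when
#'   the observable was non-finite at a perturbed point).
#' @export
local_sensitivity <- function(params, observable, param_names,
                              rel_step = 0.05) {
  stopifnot(rel_step > 0)
  f0 <- tryCatch(observable(params), error = function(e) NA_real_)
  base <- current_param_values(params, param_names)
  rows <- lapply(param_names, function(nm) {
    p0 <- base[[nm]]
    if (p0 > 0) {
      pp <- p0 * exp(rel_step); pm <- p0 * exp(-rel_step); h2 <- 2 * rel_step
      scale <- 1                       # d ln f / d ln p directly
    } else if (p0 < 0) {
      pp <- p0 * (1 - rel_step); pm <- p0 * (1 + rel_step)
      h2 <- 2 * rel_step * abs(p0); scale <- p0
    } else {
      pp <- rel_step; pm <- -rel_step; h2 <- 2 * rel_step; scale <- 1
    }
    fp <- tryCatch(observable(update_params(params, stats::setNames(pp, nm))),
                   error = function(e) NA_real_)
    fm <- tryCatch(observable(update_params(params, stats::setNames(pm, nm))),
                   error = function(e) NA_real_)
    ok <- is.finite(fp) && is.finite(fm) && is.finite(f0) && f0 != 0
    sens <- if (!ok) NA_real_
            else if (p0 > 0) (fp - fm) / (h2 * f0)
            else (fp - fm) / h2 * scale / f0
    data.frame(parameter = nm, value = p0, sensitivity = sens, ok = ok)
  })
  do.call(rbind, rows)
}

# Current scalar value of each free-parameter key.
current_param_values <- function(params, keys) {
  d <- params$dynamic
  vals <- list(
    L_HHinit = d$HH$init, L_HHaG = d$HH$aG, k_incrHH = d$HH$k_incr,
    L_KK = d$KK$init, L_KKinit = d$KK$init, L_KKaG = d$KK$aG,
    k_incrKK = d$KK$k_incr,
    L_HAraG = d$HAr$aG, k_incrHAr = d$HAr$k_incr,
    L_KAraG = d$KAr$aG, k_incrKAr = d$KAr$k_incr,
    L_HK = params$L$HK, L_HNa = params$L$HNa, L_HCl = params$L$HCl,
    L_KNa = params$L$KNa, L_KCl = params$L$KCl, L_NaCl = params$L$NaCl,
    L_NaNa = params$L$NaNa, L_ClCl = params$L$ClCl,
    k_ATPincr = params$atp$k_ATPincr, K = params$atp$K,
    C_ATP = params$atp$C_ATP, ATP = params$atp$ATP0,
    pH_in = params$init$pH_in, K_in = params$init$K_in,
    Cl_in = params$init$Cl_in, Na_in = params$init$Na_in,
    Na_out = params$init$Na_out, delta_phi = params$init$delta_phi)
  missing <- setdiff(keys, names(vals))
  if (length(missing))
    stop("unknown parameter key(s): ", paste(missing, collapse = ", "))
  vals[keys]
}
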