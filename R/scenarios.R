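# Event-driven time-course simulation of the stimulus protocols:
# KCl addition(s) and glucose energization.

#' Create a stimulus event
#'
#' @param time event time, s (>= schedule start).
#' @param kind `"kcl_addition"` (instantaneous equimolar step in external K+
#'   and Cl-) or `"glucose"` (switches on ATP production and activates the
#'   glucose-modifiable coefficients).
#' @param amount added KCl concentration, mM (required > 0 for
#'   `kcl_addition`; ignored for `glucose`).
#' @return One-row data frame with columns `time`, `kind`, `amount`.
#' @export
stimulus_event <- function(time, kind = c("kcl_addition", "glucose"),
                           amount = NA_real_) {
  kind <- match.arg(kind)
  if (time < 0) stop("event time must be >= 0")
  if (kind == "kcl_addition" && (is.na(amount) || amount < 0))
    stop("kcl_addition requires a non-negative amount (mM)")
  data.frame(time = time, kind = kind, amount = amount)
}

#' Create a stimulus schedule
#'
#' @param events data frame of events (rbind of [stimulus_event()] rows);
#'   may be empty.
#' @param span total simulated duration, s.
#' @param step output grid step, s.
#' @param t_start start time of the simulation, s.
#' @return An object of class `ion_schedule`.
#' @export
ion_schedule <- function(events = NULL, span = 1200, step = 1, t_start = 0) {
  if (is.null(events))
    events <- data.frame(time = numeric(), kind = character(),
                         amount = numeric())
  events <- events[order(events$time), , drop = FALSE]
  if (nrow(events)) {
    if (any(duplicated(events$time)))
      stop("event times must be strictly increasing")
    if (any(events$time <= t_start) || any(events$time >= t_start + span))
      stop("event times must lie strictly inside (t_start, t_start + span)")
  }
  structure(list(events = events, span = span, step = step,
                 t_start = t_start),
            class = "ion_schedule")
}

#' @export
print.ion_schedule <- function(x, ...) {
  cat(sprintf("Stimulus schedule: [%g, %g] s, output step %g s\n",
              x$t_start, x$t_start + x$span, x$step))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events))) {
      e <- x$events[i, ]
      cat(sprintf("  t = %6g s  %s%s\n", e$time, e$kind,
                  if (e$kind == "kcl_addition")
                    sprintf(" (%g mM)", e$amount) else ""))
    }
  } else cat("  (no events)\n")
  invisible(x)
}

#' The canonical stimulus schedules of the study design
#'
#' Four protocols, each parameterized by the KCl dose:
#' \describe{
#'   \item{fit}{KCl at 300 s, glucose at 600 s (the protocol under which the
#'     fitted flux data were recorded); span 1200 s.}
#'   \item{fig3}{KCl at 300 s, glucose at 660 s (the simulation protocol of
#'     the headline figure, default for the decomposition readouts);
#'     span 1200 s.}
#'   \item{validation}{KCl at 180 s, glucose at 300 s (the chloride-electrode
#'     validation runs); span 900 s.}
#'   \item{second_stimulus}{KCl at 300 s, glucose at 660 s, second KCl
#'     addition of 10 mM at 1000 s; span 1600 s.}
#' }
#'
#' @param dose first KCl dose, mM (the experiments used 0.01, 0.1, 1, 10).
#' @param step output grid step, s.
#' @param second_dose KCl amount of the second stimulus, mM.
#' @return Named list of `ion_schedule` objects.
#' @export
canonical_scenarios <- function(dose, step = 1, second_dose = 10) {
  stopifnot(dose > 0)
  list(
    fit = ion_schedule(rbind(stimulus_event(300, "kcl_addition", dose),
                             stimulus_event(600, "glucose")),
                       span = 1200, step = step),
    fig3 = ion_schedule(rbind(stimulus_event(300, "kcl_addition", dose),
                              stimulus_event(660, "glucose")),
                        span = 1200, step = step),
    validation = ion_schedule(rbind(stimulus_event(180, "kcl_addition", dose),
                                    stimulus_event(300, "glucose")),
                              span = 900, step = step),
    second_stimulus = ion_schedule(
      rbind(stimulus_event(300, "kcl_addition", dose),
            stimulus_event(660, "glucose"),
            stimulus_event(1000, "kcl_addition", second_dose)),
      span = 1600, step = step)
  )
}

#' Apply a stimulus event to a system state
#'
#' KCl addition steps the external K+ and Cl- concentrations up by the dose
#' (equimolar dissociation; bath dilution neglected). The glucose event flips
#' the energization flag: ATP production and the relaxation of the
#' glucose-modifiable coefficients start from that instant.
#'
#' @param state named state vector.
#' @param event one-row event data frame (see [stimulus_event()]).
#' @param glucose_on current energization flag.
#' @return List with updated `state` and `glucose_on`.
#' @export
apply_event <- function(state, event, glucose_on = FALSE) {
  kind <- as.character(event$kind)
  if (kind == "kcl_addition") {
    state[["K_out"]] <- state[["K_out"]] + event$amount
    state[["Cl_out"]] <- state[["Cl_out"]] + event$amount
  } else if (kind == "glucose") {
    glucose_on <- TRUE
  } else stop("unknown event kind: ", kind)
  list(state = state, glucose_on = glucose_on)
}

.out_names <- c("J_H", "J_K", "J_Na", "J_Cl", "J_Ar",
                "X_H", "X_K", "X_Na", "X_Cl", "X_Ar", "sigma")

#' Simulate a stimulus scenario
#'
#' Integrates the model piecewise between stimulus events with the stiff
#' LSODA solver, restarting exactly at each event time. Fluxes, forces and
#' the entropy-production density are recorded on the output grid. Rows at
#' event times report the post-event state.
#'
#' @param params an `ion_params` object.
#' @param schedule an `ion_schedule`.
#' @param state optional initial state vector (defaults to
#'   [initial_state()] of `params`).
#' @param rtol,atol integrator tolerances.
#' @param engine `"C"` (compiled right-hand side, default) or `"R"`
#'   (reference implementation).
#' @param buffering proton buffering mode, `"constant"` or `"dynamic"`
#'   (R engine only).
#' @param glucose_on initial energization flag (TRUE when continuing a
#'   post-glucose state).
#' @param times optional explicit output times (overrides the schedule
#'   grid; event times are always included).
#' @param maxsteps integrator step cap per output interval (runaway stiff
#'   integrations fail fast instead of stalling).
#' @return An object of class `ion_trajectory`: a data frame with `time`,
#'   the 14 state variables, fluxes `J_*` (mol m-2 s-1, outward positive),
#'   forces `X_*` (J mol-1 K-1) and `sigma`; attributes `events`, `params`,
#'   `schedule`.
#' @export
#' @examples
#' p <- parameter_set("P2a")
#' sc <- canonical_scenarios(10, step = 5)$fig3
#' tr <- simulate_fluxes(p, sc)
#' plot(tr)
simulate_fluxes <- function(params, schedule, state = NULL,
                            rtol = 1e-8, atol = 1e-10,
                            engine = c("C", "R"),
                            buffering = c("constant", "dynamic"),
                            glucose_on = FALSE, times = NULL,
                            maxsteps = 10000) {
  engine <- match.arg(engine)
  buffering <- match.arg(buffering)
  if (engine == "C" && buffering == "dynamic")
    stop("dynamic buffering is only available with engine = 'R'")
  stopifnot(inherits(params, "ion_params"), inherits(schedule, "ion_schedule"))
  if (is.null(state)) state <- initial_state(params)
  state <- state[.state_names]

  t0 <- schedule$t_start
  t_end <- t0 + schedule$span
  if (is.null(times)) {
    times <- seq(t0, t_end, by = schedule$step)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  }
  ev <- schedule$events
  times <- sort(unique(c(times, ev$time)))
  breaks <- c(t0, ev$time, t_end)

  rows <- vector("list", length(breaks) - 1L)
  for (seg in seq_len(length(breaks) - 1L)) {
    a <- breaks[seg]; b <- breaks[seg + 1L]
    seg_times <- times[times >= a & times <= b]
    if (seg_times[1] > a) seg_times <- c(a, seg_times)
    if (seg_times[length(seg_times)] < b) seg_times <- c(seg_times, b)
    parms <- as_parms_vector(params, glucose_on)
    sol <- suppressWarnings(if (engine == "C") {
      deSolve::lsoda(y = unname(state), times = seg_times,
                     func = "ionnet_rhs", parms = parms,
                     dllname = "ionNET", initfunc = "ionnet_init",
                     nout = length(.out_names), outnames = .out_names,
                     rtol = rtol, atol = atol, maxsteps = maxsteps)
    } else {
      deSolve::lsoda(y = unname(state), times = seg_times,
                     func = function(t, y, parms_unused) {
                       model_rhs(t, stats::setNames(y, .state_names), params,
                                 glucose_on = glucose_on,
                                 buffering = buffering)
                     }, parms = NULL, rtol = rtol, atol = atol,
                     maxsteps = maxsteps)
    })
    n_expected <- length(seg_times)
    if (nrow(sol) < n_expected || any(!is.finite(sol[nrow(sol), -1])))
      stop(sprintf(
        "integration failed in segment [%g, %g] s near t = %g s", a, b,
        sol[nrow(sol), 1]))
    colnames(sol) <- c("time", .state_names, .out_names)
    conc <- sol[, .state_names[1:8], drop = FALSE]
    if (any(conc <= 0)) {
      bad <- which(conc <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf("non-positive concentration (%s) at t = %g s",
                   .state_names[1:8][bad[2]], sol[bad[1], "time"]))
    }
    state <- stats::setNames(sol[nrow(sol), 1 + seq_along(.state_names)],
                             .state_names)
    # drop the final row: the next segment re-reports it (post-event)
    keep <- if (seg < length(breaks) - 1L) -nrow(sol) else TRUE
    rows[[seg]] <- as.data.frame(sol)[keep, , drop = FALSE]
    if (seg < length(breaks) - 1L) {
      upd <- apply_event(state, ev[seg, ], glucose_on)
      state <- upd$state
      glucose_on <- upd$glucose_on
    }
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  structure(traj,
            events = ev, params = params, schedule = schedule,
            engine = engine,
            class = c("ion_trajectory", "data.frame"))
}

#' @export
print.ion_trajectory <- function(x, ...) {
  sc <- attr(x, "schedule")
  cat(sprintf("Ion-flux trajectory: %d time points over [%g, %g] s (%s engine)\n",
              nrow(x), min(x$time), max(x$time), attr(x, "engine")))
  ev <- attr(x, "events")
  if (nrow(ev))
    cat("  events:", paste(sprintf("%s@%gs", ev$kind, ev$time),
                           collapse = ", "), "\n")
  cat(sprintf("  final: dphi %+.4g V, ATP %.4g mM, K_in %.4g mM, pH_in %.3f\n",
              x$dphi[nrow(x)], x$ATP[nrow(x)], x$K_in[nrow(x)],
              mM_to_ph(x$H_in[nrow(x)])))
  invisible(x)
}

#' Plot net fluxes and membrane potential of a trajectory
#'
#' Two stacked base-graphics panels: K+, H+ (and optionally Cl-) net fluxes
#' in nmol m-2 s-1, and the membrane potential; stimulus events are marked
#' with dashed vertical lines.
#'
#' @param x an `ion_trajectory`.
#' @param ions character vector of fluxes to draw.
#' @param ... passed to `matplot`.
#' @export
plot.ion_trajectory <- function(x, ions = c("K", "H", "Cl"), ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  cols <- c(K = "forestgreen", H = "blue", Na = "orange", Cl = "red")[ions]
  J <- as.matrix(x[, paste0("J_", ions), drop = FALSE]) * 1e9
  graphics::matplot(x$time, J, type = "l", lty = 1, col = cols,
                    xlab = "time (s)", ylab = "net flux (nmol m-2 s-1)", ...)
  graphics::abline(v = attr(x, "events")$time, lty = 2, col = "grey50")
  graphics::abline(h = 0, col = "grey80")
  graphics::legend("topright", legend = ions, col = cols, lty = 1, bty = "n")
  plot(x$time, x$dphi, type = "l", xlab = "time (s)",
       ylab = "membrane potential (V)")
  graphics::abline(v = attr(x, "events")$time, lty = 2, col = "grey50")
  invisible(x)
}

.variable_units <- c(
  stats::setNames(rep("mM", 8), .state_names[1:8]),
  dphi = "V", ATP = "mM",
  L_HH = "mol2/(J m2 s)", L_KK = "mol2/(J m2 s)",
  L_HAr = "mol2/(J m2 s)", L_KAr = "mol2/(J m2 s)",
  stats::setNames(rep("mol/(m2 s)", 5), .out_names[1:5]),
  stats::setNames(rep("J/(mol K)", 5), .out_names[6:10]),
  sigma = "W/(m2 K)")

#' Export a trajectory as tidy CSV with a JSON event sidecar
#'
#' Long format with columns `time_s`, `variable`, `value`, `units`,
#' `condition`; the stimulus events are written to `<path>.events.json`.
#'
#' @param traj an `ion_trajectory`.
#' @param path output CSV path.
#' @param condition condition label recorded in every row.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, condition = "unnamed") {
  vars <- setdiff(colnames(traj), "time")
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(time_s = traj$time, variable = v, value = traj[[v]],
               units = unname(.variable_units[v]), condition = condition)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  ev <- attr(traj, "events")
  jsonlite::write_json(
    list(condition = condition,
         events = if (nrow(ev)) ev else list(),
         engine = attr(traj, "engine")),
    paste0(path, ".events.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
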