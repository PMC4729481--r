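# Estimation: weighted least-squares objective over flux datasets and
# multistart particle-swarm optimization under the model's constraints.

# Parameter keys understood by update_params(), named as in the published
# tables. Straight coefficients and rates are non-negative by construction;
# cross coefficients may span sign.
.free_param_keys <- c(
  "L_HHinit", "L_HHaG", "k_incrHH",
  "L_KK", "L_KKinit", "L_KKaG", "k_incrKK",
  "L_HAraG", "k_incrHAr", "L_KAraG", "k_incrKAr",
  "L_HK", "L_HNa", "L_HCl", "L_KNa", "L_KCl", "L_NaCl",
  "L_NaNa", "L_ClCl",
  "k_ATPincr", "K", "C_ATP",
  "ATP", "pH_in", "K_in", "Cl_in", "Na_in", "Na_out", "delta_phi")

#' Return a copy of a parameter set with selected entries replaced
#'
#' Accepts a named vector with table-style keys (e.g. `L_HHaG`,
#' `k_incrHAr`, `L_ClCl`, `K_in`, `pH_in`, `delta_phi`, `ATP`) and rebuilds
#' the `ion_params` object so that all derived quantities (`k_decr` rates,
#' `k_ATPdecr`, buffering factor) stay consistent.
#'
#' @param params an `ion_params` object.
#' @param theta named numeric vector of replacements.
#' @return A new `ion_params` object.
#' @export
update_params <- function(params, theta) {
  if (length(theta) == 0) return(params)
  nm <- names(theta)
  unknown <- setdiff(nm, .free_param_keys)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  L <- params$L
  dyn <- lapply(params$dynamic, function(d) d[c("init", "aG", "k_incr")])
  atp <- params$atp[c("C_ATP", "K", "ATP_stimulus", "k_ATPincr", "ATP0")]
  init <- params$init[setdiff(names(params$init), "H_in")]
  for (k in nm) {
    v <- unname(theta[[k]])
    switch(k,
      L_HHinit = { dyn$HH$init <- v },
      L_HHaG   = { dyn$HH$aG <- v },
      k_incrHH = { dyn$HH$k_incr <- v },
      L_KK     = { dyn$KK$init <- v },
      L_KKinit = { dyn$KK$init <- v },
      L_KKaG   = { dyn$KK$aG <- v },
      k_incrKK = { dyn$KK$k_incr <- v },
      L_HAraG  = { dyn$HAr$aG <- v },
      k_incrHAr = { dyn$HAr$k_incr <- v },
      L_KAraG  = { dyn$KAr$aG <- v },
      k_incrKAr = { dyn$KAr$k_incr <- v },
      k_ATPincr = { atp$k_ATPincr <- v },
      K        = { atp$K <- v },
      C_ATP    = { atp$C_ATP <- v },
      ATP      = { atp$ATP0 <- v },
      pH_in    = { init$pH_in <- v },
      delta_phi = { init$delta_phi <- v },
      { if (startsWith(k, "L_")) L[[sub("^L_", "", k)]] <- v
        else init[[k]] <- v }
    )
  }
  ion_params(geometry = params$geometry, L = L, dynamic = dyn, atp = atp,
             init = init, variant = params$variant, name = params$name)
}

#' Define a flux-fitting problem
#'
#' Couples a flux dataset (one or more KCl conditions, K+/H+ traces) to a
#' base parameter set, the free parameters with their bound envelopes, the
#' stimulus protocol and the residual weighting. All conditions share one
#' parameter vector; only the KCl dose (parsed from the condition label)
#' differs between them.
#'
#' @param data a `flux_dataset` (outward-positive convention).
#' @param params base `ion_params`; entries not listed in `specs` stay fixed.
#' @param specs data frame with columns `name`, `lower`, `upper` — the free
#'   parameters and their bound envelopes. Straight coefficients and rate
#'   constants must have `lower >= 0`.
#' @param scenario which canonical protocol generated the data
#'   (`"fit"`, `"fig3"`, `"validation"`) or a function `dose -> ion_schedule`.
#' @param variant `"M2"` (forces `L_KAr = 0`; default) or `"M1"`.
#' @param weighting `"mean_square"` weights each (condition, ion) trace by
#'   the inverse of its mean squared flux, so traces of different magnitude
#'   contribute comparably; `"none"` is the unweighted sum of squares.
#' @param rtol,atol integrator tolerances used inside the objective.
#' @return List of class `fit_problem`.
#' @export
fit_problem <- function(data, params, specs,
                        scenario = "fit",
                        variant = params$variant,
                        weighting = c("mean_square", "none"),
                        rtol = 1e-6, atol = 1e-8) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(data, "flux_dataset"))
  if (!all(c("name", "lower", "upper") %in% names(specs)))
    stop("specs needs columns name, lower, upper")
  unknown <- setdiff(specs$name, .free_param_keys)
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "))
  if (any(specs$lower >= specs$upper))
    stop("each spec needs lower < upper")
  straight <- c("L_HHinit", "L_HHaG", "L_KK", "L_KKinit", "L_KKaG",
                "L_NaNa", "L_ClCl")
  bad <- specs$name[specs$name %in% straight & specs$lower < 0]
  if (length(bad))
    stop("straight coefficients must have lower bound >= 0: ",
         paste(bad, collapse = ", "))
  if (variant == "M2" && any(specs$name %in% c("L_KAraG", "k_incrKAr")))
    stop("variant M2 fixes L_KAr = 0; remove L_KAraG/k_incrKAr from specs")

  sched_fun <- if (is.function(scenario)) scenario
               else function(dose) canonical_scenarios(dose)[[scenario]]

  conditions <- unique(data$condition)
  traces <- list()
  for (cond in conditions) {
    dose <- condition_dose(cond)
    for (ion in unique(data$ion[data$condition == cond])) {
      sel <- data$condition == cond & data$ion == ion
      y <- data$flux_nmol_m2_s[sel]
      w <- if (weighting == "mean_square") 1 / max(mean(y^2), 1e-300) else 1
      traces[[paste(cond, ion, sep = ".")]] <-
        list(condition = cond, dose = dose, ion = ion,
             time = data$time_s[sel], flux = y, weight = w)
    }
  }
  structure(list(data = data, params = params, specs = specs,
                 scenario = sched_fun, variant = variant,
                 weighting = weighting, traces = traces,
                 conditions = conditions,
                 rtol = rtol, atol = atol),
            class = "fit_problem")
}

# Simulate all conditions of a problem at a parameter vector; returns a list
# of trajectories keyed by condition (or signals an error).
simulate_problem <- function(theta, problem, step = NULL) {
  p <- update_params(problem$params, theta)
  out <- list()
  for (cond in problem$conditions) {
    dose <- condition_dose(cond)
    sched <- problem$scenario(dose)
    t_data <- sort(unique(problem$data$time_s[problem$data$condition == cond]))
    times <- sort(unique(c(sched$t_start, sched$t_start + sched$span, t_data)))
    out[[cond]] <- simulate_fluxes(p, sched, times = times,
                                   rtol = problem$rtol, atol = problem$atol)
  }
  out
}

#' Weighted least-squares objective of a fit problem
#'
#' Simulates every condition with the shared parameter vector and returns
#' the weighted sum of squared residuals between simulated and measured
#' net fluxes (nmol m-2 s-1) at the data timestamps. A failed simulation
#' (stiff corner, non-positive concentration) yields a large finite penalty
#' `1e6 * (1 + unfinished fraction of the horizon)` so swarm optimization
#' can continue.
#'
#' @param theta named numeric vector of the free parameters (names matching
#'   `problem$specs$name`).
#' @param problem a [fit_problem()].
#' @return Non-negative scalar.
#' @export
flux_objective <- function(theta, problem) {
  if (is.null(names(theta))) names(theta) <- problem$specs$name
  sims <- tryCatch(simulate_problem(theta, problem), error = identity)
  if (inherits(sims, "error")) {
    t_fail <- suppressWarnings(
      as.numeric(sub(".*t = ([0-9.eE+-]+) s.*", "\\1",
                     conditionMessage(sims))))
    span <- problem$scenario(1)$span
    shortfall <- if (is.finite(t_fail)) max(0, 1 - t_fail / span) else 1
    return(1e6 * (1 + shortfall))
  }
  total <- 0
  for (tr in problem$traces) {
    traj <- sims[[tr$condition]]
    sim_flux <- traj[[paste0("J_", tr$ion)]][match(tr$time, traj$time)] * 1e9
    total <- total + tr$weight * sum((sim_flux - tr$flux)^2)
  }
  total
}

#' Particle swarm optimization
#'
#' Standard global-best PSO with inertia and cognitive/social acceleration,
#' velocity clamping, and reflection-free position clamping to the bounds.
#' Dimensions whose lower bound is strictly positive are searched in log10
#' space (the phenomenological coefficients span many decades). Terminates
#' at the iteration limit or when the standard deviation of the personal
#' best objectives falls below `stall_sd`. Deterministic for a fixed seed.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper numeric bound vectors (finite, `lower < upper`).
#' @param swarm_size number of particles (>= 2).
#' @param iter_max iteration limit.
#' @param stall_sd termination threshold on the swarm objective spread.
#' @param seed integer seed.
#' @param inertia,c_cog,c_soc velocity-update constants (constriction-type
#'   defaults).
#' @param vmax_frac velocity clamp as a fraction of the bound width.
#' @return List with `par`, `value`, `iterations`, `converged`,
#'   `history` (best value per iteration), `seed`.
#' @export
pso <- function(fn, lower, upper, swarm_size = 40, iter_max = 400,
                stall_sd = 1e-6, seed = 1L, inertia = 0.729,
                c_cog = 1.49445, c_soc = 1.49445, vmax_frac = 0.5) {
  d <- length(lower)
  stopifnot(d >= 1, length(upper) == d, all(is.finite(c(lower, upper))),
            all(lower < upper), swarm_size >= 2)
  par_names <- names(lower)
  logdim <- lower > 0
  lo <- lower; lo[logdim] <- log10(lower[logdim])
  hi <- upper; hi[logdim] <- log10(upper[logdim])
  back <- function(x) { x[logdim] <- 10^x[logdim]; x }

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  width <- hi - lo
  vmax <- vmax_frac * width
  pos <- t(replicate(swarm_size, stats::runif(d, lo, hi)))
  if (d == 1) pos <- matrix(pos, ncol = 1)
  vel <- t(replicate(swarm_size, stats::runif(d, -vmax, vmax)))
  if (d == 1) vel <- matrix(vel, ncol = 1)

  evaluate <- function(x) {
    v <- fn(stats::setNames(back(x), par_names))
    if (!is.finite(v)) 1e12 else v
  }
  pbest <- pos
  pbest_val <- apply(pos, 1, evaluate)
  g <- which.min(pbest_val)
  gbest <- pos[g, ]; gbest_val <- pbest_val[g]
  history <- numeric(iter_max)
  converged <- FALSE
  iter <- 0L
  while (iter < iter_max) {
    iter <- iter + 1L
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    vel <- inertia * vel +
      c_cog * r1 * (pbest - pos) +
      c_soc * r2 * (matrix(gbest, swarm_size, d, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, matrix(-vmax, swarm_size, d, byrow = TRUE)),
                matrix(vmax, swarm_size, d, byrow = TRUE))
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lo, swarm_size, d, byrow = TRUE)),
                matrix(hi, swarm_size, d, byrow = TRUE))
    vals <- apply(pos, 1, evaluate)
    improved <- vals < pbest_val
    pbest[improved, ] <- pos[improved, ]
    pbest_val[improved] <- vals[improved]
    g <- which.min(pbest_val)
    if (pbest_val[g] < gbest_val) {
      gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
    }
    history[iter] <- gbest_val
    if (stats::sd(pbest_val) < stall_sd) { converged <- TRUE; break }
  }
  list(par = stats::setNames(back(gbest), par_names), value = gbest_val,
       iterations = iter, converged = converged,
       history = history[seq_len(iter)], seed = seed)
}

# Draw randomized bounds within the spec envelope: log-uniform for strictly
# positive envelopes, uniform otherwise. Run 1 of a multistart uses the full
# envelope.
draw_bounds <- function(specs) {
  lo <- specs$lower; hi <- specs$upper
  for (i in seq_along(lo)) {
    if (lo[i] > 0) {
      pair <- sort(10^stats::runif(2, log10(lo[i]), log10(hi[i])))
    } else {
      pair <- sort(stats::runif(2, lo[i], hi[i]))
    }
    if (diff(pair) < 1e-12 * max(abs(pair), 1)) next
    lo[i] <- pair[1]; hi[i] <- pair[2]
  }
  list(lower = lo, upper = hi)
}

#' Fit phenomenological coefficients to flux data
#'
#' Multistart particle-swarm estimation: `n_starts` independent PSO runs
#' with randomized start positions and randomized bounds drawn inside the
#' spec envelope (the first run uses the full envelope). The best run wins.
#' If any winning parameter sits on its envelope bound, that bound is
#' extended by a factor of 100 and one follow-up estimation is run (at most
#' `max_extensions` rounds).
#'
#' @param problem a [fit_problem()].
#' @param n_starts number of PSO restarts.
#' @param swarm_size,iter_max,stall_sd PSO controls (see [pso()]).
#' @param seed integer master seed; run `r` uses `seed + r`.
#' @param max_extensions maximum boundary-extension rounds.
#' @param verbose print per-run progress.
#' @return An object of class `ion_fit`.
#' @export
fit_fluxes <- function(problem, n_starts = 50, swarm_size = 40,
                       iter_max = 400, stall_sd = 1e-6, seed = 1L,
                       max_extensions = 2, verbose = FALSE) {
  stopifnot(inherits(problem, "fit_problem"), n_starts >= 1)
  specs <- problem$specs
  fn <- function(theta) flux_objective(theta, problem)
  envelope <- list(lower = stats::setNames(specs$lower, specs$name),
                   upper = stats::setNames(specs$upper, specs$name))

  run_multistart <- function(env, n_runs, seed0) {
    runs <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      b <- if (r == 1) env else {
        old_seed <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv()) else NULL
        set.seed(seed0 + 7000L + r)
        out <- draw_bounds(data.frame(lower = env$lower, upper = env$upper))
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
        list(lower = stats::setNames(out$lower, specs$name),
             upper = stats::setNames(out$upper, specs$name))
      }
      runs[[r]] <- pso(fn, b$lower, b$upper, swarm_size = swarm_size,
                       iter_max = iter_max, stall_sd = stall_sd,
                       seed = seed0 + r)
      if (verbose)
        message(sprintf("  run %d/%d: objective %.6g%s", r, n_runs,
                        runs[[r]]$value,
                        if (runs[[r]]$converged) " (stalled)" else ""))
    }
    runs
  }

  extension_log <- list()
  runs <- run_multistart(envelope, n_starts, seed)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  round <- 0L
  repeat {
    at_lo <- abs(best$par - envelope$lower) <=
      1e-6 * pmax(abs(envelope$lower), 1e-300)
    at_hi <- abs(best$par - envelope$upper) <=
      1e-6 * pmax(abs(envelope$upper), 1e-300)
    hit <- (at_lo & envelope$lower != 0) | at_hi
    if (!any(hit) || round >= max_extensions) break
    round <- round + 1L
    for (i in which(hit)) {
      nm <- specs$name[i]
      if (at_hi[i]) envelope$upper[i] <- envelope$upper[i] * 100
      if (at_lo[i] && envelope$lower[i] != 0) {
        envelope$lower[i] <- if (envelope$lower[i] > 0)
          envelope$lower[i] / 100 else envelope$lower[i] * 100
      }
      extension_log[[length(extension_log) + 1L]] <-
        list(round = round, parameter = nm,
             side = if (at_hi[i]) "upper" else "lower")
    }
    follow <- run_multistart(envelope, 1L, seed + 9000L * round)
    runs <- c(runs, follow)
    cand <- follow[[1]]
    if (cand$value < best$value) best <- cand
  }

  fitted_params <- update_params(problem$params, best$par)
  structure(list(par = best$par, objective = best$value,
                 problem = problem, params = fitted_params,
                 runs = data.frame(
                   run = seq_along(runs),
                   objective = vapply(runs, `[[`, numeric(1), "value"),
                   iterations = vapply(runs, `[[`, numeric(1), "iterations"),
                   seed = vapply(runs, `[[`, numeric(1), "seed")),
                 extension_log = extension_log,
                 seed = seed, n_starts = n_starts),
            class = "ion_fit")
}
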