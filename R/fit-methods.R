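# S3 methods for fitted ion-flux models.

#' @export
print.ion_fit <- function(x, ...) {
  cat(sprintf("Ion-flux model fit (%s, variant %s)\n",
              x$problem$params$name, x$problem$variant))
  cat(sprintf("  %d free parameter(s), %d PSO run(s), objective %.6g\n",
              length(x$par), nrow(x$runs), x$objective))
  print(signif(x$par, 5))
  if (length(x$extension_log))
    cat(sprintf("  boundary extensions: %d\n", length(x$extension_log)))
  invisible(x)
}

#' @export
coef.ion_fit <- function(object, ...) object$par

#' @export
deviance.ion_fit <- function(object, ...) object$objective

#' @export
summary.ion_fit <- function(object, ...) {
  specs <- object$problem$specs
  tab <- data.frame(parameter = specs$name,
                    estimate = unname(object$par[specs$name]),
                    lower = specs$lower, upper = specs$upper)
  tab$at_bound <- with(tab, estimate <= lower * (1 + 1e-6) & lower > 0 |
                         estimate >= upper * (1 - 1e-6))
  res <- list(coefficients = tab, objective = object$objective,
              runs = object$runs, n_traces = length(object$problem$traces),
              onsager = validate_onsager(object$params),
              extension_log = object$extension_log)
  class(res) <- "summary.ion_fit"
  res
}

#' @export
print.summary.ion_fit <- function(x, ...) {
  cat("Ion-flux model fit summary\n")
  cat(sprintf("  objective: %.6g over %d trace(s)\n", x$objective, x$n_traces))
  cat(sprintf("  PSO runs: %d (best %.6g, median %.6g)\n", nrow(x$runs),
              min(x$runs$objective), stats::median(x$runs$objective)))
  print(x$coefficients, row.names = FALSE)
  print(x$onsager)
  invisible(x)
}

#' Model-predicted fluxes at the data timestamps
#'
#' @param object an `ion_fit`.
#' @param newdata optional `flux_dataset` defining conditions and times
#'   (defaults to the fitted data).
#' @param ... unused.
#' @return A `flux_dataset` of predicted net fluxes (nmol m-2 s-1).
#' @export
predict.ion_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$problem$data else newdata
  problem <- object$problem
  sims <- simulate_problem(object$par, fit_problem(
    data, problem$params, problem$specs, scenario = problem$scenario,
    variant = problem$variant, weighting = problem$weighting,
    rtol = problem$rtol, atol = problem$atol))
  out <- data
  for (cond in unique(data$condition)) {
    traj <- sims[[cond]]
    for (ion in unique(data$ion[data$condition == cond])) {
      sel <- data$condition == cond & data$ion == ion
      out$flux_nmol_m2_s[sel] <-
        traj[[paste0("J_", ion)]][match(data$time_s[sel], traj$time)] * 1e9
    }
  }
  attr(out, "provenance") <- list(source = "prediction",
                                  params = object$params$name)
  out
}

#' @export
residuals.ion_fit <- function(object, ...) {
  pred <- predict(object)
  object$problem$data$flux_nmol_m2_s - pred$flux_nmol_m2_s
}

#' @export
fitted.ion_fit <- function(object, ...) predict(object)$flux_nmol_m2_s

#' Plot data and fitted flux traces
#'
#' One panel per condition: measured net fluxes (points) and the fitted
#' model curves (lines), colour-coded by ion.
#'
#' @param x an `ion_fit`.
#' @param ... unused.
#' @export
plot.ion_fit <- function(x, ...) {
  data <- x$problem$data
  pred <- predict(x)
  conds <- unique(data$condition)
  nc <- length(conds)
  old <- graphics::par(mfrow = c(ceiling(nc / 2), min(nc, 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  cols <- c(K = "forestgreen", H = "blue", Na = "orange", Cl = "red")
  for (cond in conds) {
    sel <- data$condition == cond
    plot(data$time_s[sel], data$flux_nmol_m2_s[sel],
         col = cols[data$ion[sel]], pch = 16, cex = 0.4,
         xlab = "time (s)", ylab = "net flux (nmol m-2 s-1)", main = cond)
    for (ion in unique(data$ion[sel])) {
      s2 <- sel & data$ion == ion
      graphics::lines(pred$time_s[s2], pred$flux_nmol_m2_s[s2],
                      col = cols[ion], lwd = 2)
    }
    graphics::abline(h = 0, col = "grey80")
  }
  invisible(x)
}

#' Simulate synthetic datasets from a fitted model
#'
#' Parametric-bootstrap style: regenerates the fitted conditions from the
#' fitted parameters with the given noise model.
#'
#' @param object an `ion_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (per-replicate seeds are derived from it).
#' @param noise a [noise_model()]; its seed field is overridden.
#' @param ... unused.
#' @return A list of `flux_dataset` objects of length `nsim`.
#' @export
simulate.ion_fit <- function(object, nsim = 1, seed = 1L,
                             noise = noise_model(), ...) {
  problem <- object$problem
  data <- problem$data
  step <- min(diff(sort(unique(data$time_s))))
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    sets <- lapply(unique(data$condition), function(cond) {
      dose <- condition_dose(cond)
      ions <- unique(data$ion[data$condition == cond])
      synthesize_fluxes(object$params, problem$scenario(dose),
                        sample_step = step,
                        noise = noise_model(noise$relative_sd, noise$floor_sd,
                                            seed = seed * 1000L + i * 10L +
                                              match(cond, unique(data$condition))),
                        ions = ions, condition = cond)
    })
    out[[i]] <- new_flux_dataset(do.call(rbind, sets),
                                 provenance = list(source = "simulate.ion_fit",
                                                   seed = seed, replicate = i))
  }
  out
}
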