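test_that("objective is near zero at the generating parameters", {
  prob <- fit_problem(bench_data(), bench_params(), bench_specs(),
                      scenario = "fit")
  expect_lt(flux_objective(bench_truth, prob), 1e-4)
})

test_that("perturbing one data point raises the objective by its weighted square", {
  data <- bench_data(doses = 1, ions = c("K", "H"), step = 50)
  prob <- fit_problem(data, bench_params(),
                      data.frame(name = "L_KK", lower = 2e-9, upper = 2e-7),
                      scenario = "fit")
  v0 <- flux_objective(c(L_KK = 2e-8), prob)
  eps <- 100
  data2 <- data
  i <- which(data2$ion == "K")[5]
  data2$flux_nmol_m2_s[i] <- data2$flux_nmol_m2_s[i] + eps
  prob2 <- fit_problem(data2, bench_params(),
                       data.frame(name = "L_KK", lower = 2e-9, upper = 2e-7),
                       scenario = "fit")
  w <- prob2$traces[["KCl_1mM.K"]]$weight
  # residual at the generating parameters is integrator-level noise, so the
  # increase is w * eps^2 up to a negligible cross term
  delta <- flux_objective(c(L_KK = 2e-8), prob2) - v0
  expect_equal(delta / (w * eps^2), 1, tolerance = 1e-3)
})

test_that("objective matches an independent residual-loop computation", {
  data <- bench_data(noise = noise_model(0.05, 2, seed = 3))
  prob <- fit_problem(data, bench_params(), bench_specs(), scenario = "fit")
  theta <- c(L_KK = 3e-8, L_ClCl = 1.5e-7, L_HHinit = 4e-7)

  # independent oracle: explicit loop over traces
  p <- update_params(bench_params(), theta)
  expected <- 0
  for (cond in unique(data$condition)) {
    dose <- condition_dose(cond)
    tdat <- sort(unique(data$time_s[data$condition == cond]))
    tr <- simulate_fluxes(p, canonical_scenarios(dose)$fit,
                          times = unique(c(0, tdat, 1200)),
                          rtol = 1e-6, atol = 1e-8)
    for (ion in unique(data$ion)) {
      sel <- data$condition == cond & data$ion == ion
      y <- data$flux_nmol_m2_s[sel]
      sim <- tr[[paste0("J_", ion)]][match(data$time_s[sel], tr$time)] * 1e9
      expected <- expected + sum((sim - y)^2) / mean(y^2)
    }
  }
  expect_equal(flux_objective(theta, prob), expected, tolerance = 1e-8)
})

test_that("failed simulations yield a large finite penalty", {
  # an extreme coefficient drives the internal proton pool to depletion
  prob <- fit_problem(bench_data(doses = 1, step = 100), parameter_set("P2a"),
                      data.frame(name = "L_ClCl", lower = 1e-9,
                                 upper = 1e-5),
                      scenario = "fit")
  v <- flux_objective(c(L_ClCl = 3e-8), prob)
  expect_true(is.finite(v))
  expect_gte(v, 1e6)
})

test_that("problem construction enforces the estimation constraints", {
  data <- bench_data(doses = 1, step = 100)
  p <- bench_params()
  expect_error(fit_problem(data, p,
                           data.frame(name = "L_KK", lower = -1, upper = 1)),
               "lower bound >= 0")
  expect_error(fit_problem(data, p,
                           data.frame(name = "L_KAraG", lower = -1e-5,
                                      upper = 1e-5), variant = "M2"),
               "M2")
  expect_error(fit_problem(data, p,
                           data.frame(name = "bogus", lower = 0, upper = 1)),
               "unknown free parameter")
  expect_error(fit_problem(data, p,
                           data.frame(name = "L_KK", lower = 1, upper = 1)),
               "lower < upper")
})

test_that("particle swarm finds analytic optima and is seed-deterministic", {
  sphere <- function(x) sum(x^2)
  r <- pso(sphere, lower = rep(-5, 5), upper = rep(5, 5),
           swarm_size = 40, iter_max = 400, seed = 1)
  expect_lt(r$value, 1e-6)

  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  r2 <- pso(rosen, lower = c(-2, -2), upper = c(2, 2),
            swarm_size = 40, iter_max = 400, seed = 1)
  expect_lt(r2$value, 1e-4)
  expect_equal(unname(r2$par), c(1, 1), tolerance = 0.01)

  r3 <- pso(sphere, lower = rep(-5, 5), upper = rep(5, 5),
            swarm_size = 40, iter_max = 400, seed = 1)
  expect_identical(r, r3)
})

test_that("every evaluated particle position respects the bounds", {
  seen <- new.env(); seen$x <- list()
  fn <- function(x) { seen$x[[length(seen$x) + 1L]] <- x; sum((x - 2)^2) }
  lo <- c(-1, 1e-4); hi <- c(3, 10)   # second dimension searched in log10
  pso(fn, lower = lo, upper = hi, swarm_size = 8, iter_max = 25, seed = 4)
  X <- do.call(rbind, seen$x)
  expect_true(all(X[, 1] >= lo[1] - 1e-12 & X[, 1] <= hi[1] + 1e-12))
  expect_true(all(X[, 2] >= lo[2] * (1 - 1e-9) & X[, 2] <= hi[2] * (1 + 1e-9)))
})

test_that("multistart reduces to one swarm run and improves monotonically", {
  data <- bench_data(doses = 1, ions = "K", step = 100)
  specs <- data.frame(name = "L_KK", lower = 2e-9, upper = 2e-7)
  prob <- fit_problem(data, bench_params(), specs, scenario = "fit")

  fit1 <- fit_fluxes(prob, n_starts = 1, swarm_size = 6, iter_max = 10,
                     seed = 5, max_extensions = 0)
  direct <- pso(function(th) flux_objective(th, prob),
                lower = c(L_KK = 2e-9), upper = c(L_KK = 2e-7),
                swarm_size = 6, iter_max = 10, seed = 6)   # run seed = 5 + 1
  expect_equal(fit1$objective, direct$value)
  expect_equal(fit1$par, direct$par)

  objs <- vapply(1:3, function(n)
    fit_fluxes(prob, n_starts = n, swarm_size = 6, iter_max = 10,
               seed = 5, max_extensions = 0)$objective, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("a bound-riding optimum triggers the hundredfold extension", {
  data <- bench_data(doses = 1, ions = c("K", "H"), step = 50)
  # envelope placed entirely above the generating value: the optimum rides
  # the lower bound until it is extended by 100x
  specs <- data.frame(name = "L_KK", lower = 5e-8, upper = 2e-7)
  prob <- fit_problem(data, bench_params(), specs, scenario = "fit")
  fit <- fit_fluxes(prob, n_starts = 2, swarm_size = 8, iter_max = 25,
                    seed = 2, max_extensions = 2)
  expect_gt(length(fit$extension_log), 0)
  expect_identical(fit$extension_log[[1]]$parameter, "L_KK")
  expect_identical(fit$extension_log[[1]]$side, "lower")
  # the true value 2e-8 is inside the extended envelope and is found
  expect_equal(unname(fit$par["L_KK"]), 2e-8, tolerance = 0.1)
})

test_that("fitted model objects expose the standard accessor methods", {
  data <- bench_data(doses = c(0.1, 10), ions = c("K", "H"), step = 50)
  specs <- data.frame(name = "L_KK", lower = 2e-9, upper = 2e-7)
  prob <- fit_problem(data, bench_params(), specs, scenario = "fit")
  fit <- fit_fluxes(prob, n_starts = 2, swarm_size = 8, iter_max = 20,
                    seed = 9)
  expect_s3_class(fit, "ion_fit")
  expect_named(coef(fit), "L_KK")
  expect_equal(deviance(fit), fit$objective)
  expect_equal(unname(coef(fit)["L_KK"]), 2e-8, tolerance = 0.05)

  pred <- predict(fit)
  expect_s3_class(pred, "flux_dataset")
  expect_identical(pred$time_s, data$time_s)
  res <- residuals(fit)
  expect_equal(res, data$flux_nmol_m2_s - pred$flux_nmol_m2_s)
  expect_lt(sqrt(mean(res^2)) / sqrt(mean(data$flux_nmol_m2_s^2)), 0.05)

  s <- summary(fit)
  expect_s3_class(s, "summary.ion_fit")
  expect_false(s$coefficients$at_bound[1])

  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), dim(data))
  expect_false(identical(sims[[1]]$flux_nmol_m2_s,
                         sims[[2]]$flux_nmol_m2_s))
})
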