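test_that("canonical schedules encode the study protocols", {
  sc <- canonical_scenarios(1)
  expect_named(sc, c("fit", "fig3", "validation", "second_stimulus"))
  expect_equal(sc$fit$events$time, c(300, 600))
  expect_equal(sc$fit$events$kind, c("kcl_addition", "glucose"))
  expect_equal(sc$fit$events$amount[1], 1)
  expect_equal(sc$fig3$events$time, c(300, 660))
  expect_equal(sc$validation$events$time, c(180, 300))

  s2 <- canonical_scenarios(0.01)$second_stimulus
  expect_equal(s2$events$time, c(300, 660, 1000))
  expect_equal(s2$events$amount, c(0.01, NA, 10))
  for (s in canonical_scenarios(10))
    expect_true(all(diff(s$events$time) > 0))
  expect_error(ion_schedule(rbind(stimulus_event(500, "kcl_addition", 1),
                                  stimulus_event(500, "glucose"))),
               "strictly increasing")
})

test_that("stimulus events transform the state as an equimolar salt step", {
  st <- initial_state(parameter_set("P2a"))
  ev <- stimulus_event(300, "kcl_addition", 10)
  out <- apply_event(st, ev)
  expect_equal(out$state[["K_out"]], 10.1)
  expect_equal(out$state[["Cl_out"]], 10.1)
  expect_false(out$glucose_on)
  # all other state entries untouched
  keep <- setdiff(names(st), c("K_out", "Cl_out"))
  expect_identical(out$state[keep], st[keep])

  gl <- apply_event(st, stimulus_event(600, "glucose"))
  expect_true(gl$glucose_on)
  expect_identical(gl$state, st)

  null_ev <- apply_event(st, stimulus_event(300, "kcl_addition", 0))
  expect_identical(null_ev$state, st)
  expect_error(apply_event(st, data.frame(time = 1, kind = "caffeine",
                                          amount = 1)), "unknown event")
  expect_error(stimulus_event(300, "kcl_addition", -1), "amount")
})

test_that("zero-force equilibrium stays constant over a simulated span", {
  eq <- equilibrium_params()
  tr <- simulate_fluxes(eq, ion_schedule(span = 500, step = 50))
  for (v in c("K_in", "K_out", "dphi", "ATP", "H_in"))
    expect_equal(tr[[v]], rep(tr[[v]][1], nrow(tr)), tolerance = 1e-9)
  expect_true(all(abs(tr$J_K) < 1e-15))
})

test_that("ATP follows its closed-form relaxation after glucose", {
  p <- parameter_set("P2a")
  tr <- simulate_fluxes(p, canonical_scenarios(10)$fit)
  expect_true(all(tr$ATP[tr$time < 600] == 2.477))   # frozen when starved
  post <- tr[tr$time >= 600, ]
  closed <- 2.5 + (2.477 - 2.5) * exp(-4 * (post$time - 600))
  expect_equal(post$ATP, closed, tolerance = 1e-7)
})

test_that("glucose energization reproduces the qualitative flux signature", {
  p <- parameter_set("P2a")
  tr <- simulate_fluxes(p, canonical_scenarios(10)$fig3)
  post <- tr[tr$time >= 665 & tr$time <= 900, ]
  expect_true(all(post$J_K < 0))          # K+ influx (outward positive)
  # sustained H+ efflux once the pump coefficient has ramped up
  expect_true(all(post$J_H[post$time >= 680] > 0))
  # membrane potential decreases after glucose
  dphi_pre <- tr$dphi[tr$time == 659]
  expect_lt(min(tr$dphi[tr$time > 660 & tr$time < 700]), dphi_pre)
})

test_that("matter is conserved between stimulus events", {
  p <- parameter_set("P2a")
  tr <- simulate_fluxes(p, canonical_scenarios(10)$fig3)
  g <- p$geometry
  windows <- list(c(0, 299), c(300, 659), c(660, 1200))
  for (w in windows) {
    seg <- tr[tr$time >= w[1] & tr$time <= w[2], ]
    for (ion in c("K", "Na", "Cl")) {
      tot <- g$V_out * seg[[paste0(ion, "_out")]] +
        g$V_in * seg[[paste0(ion, "_in")]]
      expect_lt((max(tot) - min(tot)) / mean(tot), 1e-8)
    }
  }
})

test_that("membrane potential change equals the integrated charge flux", {
  p <- parameter_set("P2a")
  tr <- simulate_fluxes(p, canonical_scenarios(10)$fig3)
  g <- p$geometry
  for (w in list(c(100, 299), c(801, 1100))) {
    seg <- tr[tr$time >= w[1] & tr$time <= w[2], ]
    net <- seg$J_H + seg$J_K + seg$J_Na - seg$J_Cl
    integral <- sum((head(net, -1) + tail(net, -1)) / 2 * diff(seg$time))
    lhs <- seg$dphi[nrow(seg)] - seg$dphi[1]
    rhs <- -(2 * g$F / g$Cm) * integral
    expect_equal(lhs, rhs, tolerance = 0.05)
  }
})

test_that("a single-cation reduced model relaxes to the Nernst potential", {
  solo <- ion_params(
    dynamic = list(KK = list(init = 1e-8)),
    init = list(K_in = 100, K_out = 1, delta_phi = 0, pH_in = 5.5,
                H_out = ph_to_mM(5.5), Na_in = 1, Na_out = 1,
                Cl_in = 1, Cl_out = 1),
    atp = list(C_ATP = 0.3, K = 0, ATP_stimulus = 2.5, k_ATPincr = 0,
               ATP0 = 0.3))
  tr <- simulate_fluxes(solo, ion_schedule(span = 100, step = 10))
  final <- tr[nrow(tr), ]
  expect_lt(abs(final$X_K), 1e-6)
  g <- solo$geometry
  nernst <- -(g$R * g$T / g$F) * log(final$K_in / final$K_out)
  expect_equal(final$dphi, nernst, tolerance = 1e-8)
})

test_that("entropy production is non-negative under a PSD coefficient matrix", {
  # diagonal-dominant set with an in-bound H/Cl cross term
  psd <- ion_params(
    L = list(HCl = 1e-8, ClCl = 2e-7, NaNa = 1e-9),
    dynamic = list(HH = list(init = 3e-7), KK = list(init = 2e-8)),
    atp = list(C_ATP = 0.3, K = 0, ATP_stimulus = 2.5, k_ATPincr = 0,
               ATP0 = 0.3),
    init = list(K_in = 75, K_out = 0.1, Cl_in = 0.5, Cl_out = 0.1,
                Na_in = 15, Na_out = 0.01, pH_in = 6.5, delta_phi = -0.12))
  expect_true(validate_onsager(psd)$psd)
  tr <- simulate_fluxes(psd, ion_schedule(
    events = stimulus_event(100, "kcl_addition", 5), span = 400, step = 2))
  expect_true(all(entropy_production(tr) >= -1e-18))
})

test_that("the output grid can be refined without changing the solution", {
  p <- bench_params()
  sc1 <- canonical_scenarios(1, step = 20)$fit
  sc2 <- canonical_scenarios(1, step = 10)$fit
  t1 <- simulate_fluxes(p, sc1)
  t2 <- simulate_fluxes(p, sc2)
  shared <- intersect(t1$time, t2$time)
  i1 <- match(shared, t1$time); i2 <- match(shared, t2$time)
  for (v in c("K_in", "dphi", "ATP", "J_K"))
    expect_equal(t1[[v]][i1], t2[[v]][i2], tolerance = 1e-6)
})

test_that("the dynamics are invariant under time translation", {
  p <- bench_params()
  base <- ion_schedule(rbind(stimulus_event(100, "kcl_addition", 1),
                             stimulus_event(250, "glucose")),
                       span = 400, step = 10)
  shifted <- ion_schedule(rbind(stimulus_event(600, "kcl_addition", 1),
                                stimulus_event(750, "glucose")),
                          span = 400, step = 10, t_start = 500)
  t1 <- simulate_fluxes(p, base)
  t2 <- simulate_fluxes(p, shifted)
  expect_equal(t2$time, t1$time + 500)
  for (v in c("K_in", "K_out", "dphi", "ATP", "J_K", "J_H"))
    expect_lt(max(abs(t2[[v]] - t1[[v]])),
              1e-7 * max(abs(t1[[v]])) + 1e-20)
})

test_that("R and C engines integrate to the same trajectory", {
  p <- parameter_set("P2a")
  sc <- canonical_scenarios(10, step = 50)$fig3
  trC <- simulate_fluxes(p, sc, engine = "C")
  trR <- simulate_fluxes(p, sc, engine = "R")
  for (v in c("K_in", "H_in", "dphi", "ATP", "L_HH", "J_K", "J_H", "sigma"))
    expect_equal(trR[[v]], trC[[v]], tolerance = 1e-5)
})

test_that("non-positive concentrations raise a domain error", {
  p <- parameter_set("P2a")
  st <- initial_state(p)
  st[["K_in"]] <- -1
  expect_error(simulate_fluxes(p, ion_schedule(span = 10, step = 1),
                               state = st),
               "non-positive concentration|integration failed")
})

test_that("trajectory export writes tidy CSV with an event sidecar", {
  p <- bench_params()
  tr <- simulate_fluxes(p, canonical_scenarios(1, step = 100)$fit)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path, condition = "KCl_1mM")
  long <- read.csv(path)
  expect_identical(names(long),
                   c("time_s", "variable", "value", "units", "condition"))
  expect_true(all(c("K_in", "J_K", "sigma") %in% long$variable))
  ev <- jsonlite::read_json(paste0(path, ".events.json"))
  expect_equal(length(ev$events), 2)
  expect_equal(ev$events[[1]]$kind, "kcl_addition")
})
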