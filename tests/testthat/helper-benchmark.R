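# Shared fixtures: a well-conditioned reduced M2 model used as the ground
# truth for estimator benchmarks (synthetic by design: strong proton
# buffering, no H+/Cl- coupling, moderate coefficient magnitudes), plus a
# small data-generation helper.

bench_params <- function() {
  ion_params(
    geometry = cell_geometry(pbc = 20000),
    L = list(NaNa = 1e-9, ClCl = 2e-7),
    dynamic = list(HH = list(init = 3e-7, aG = 3e-6, k_incr = 3e-8),
                   KK = list(init = 2e-8),
                   HAr = list(aG = 5e-7, k_incr = 5e-9)),
    atp = list(C_ATP = 0.3, K = 0, ATP_stimulus = 2.5, k_ATPincr = 10,
               ATP0 = 1),
    init = list(K_in = 75, K_out = 0.1, Cl_in = 0.5, Cl_out = 0.1,
                Na_in = 15, Na_out = 0.01, pH_in = 6.5, delta_phi = -0.15),
    variant = "M2", name = "bench")
}

bench_truth <- c(L_KK = 2e-8, L_ClCl = 2e-7, L_HHinit = 3e-7)

bench_specs <- function() {
  data.frame(name = names(bench_truth),
             lower = unname(bench_truth) / 10,
             upper = unname(bench_truth) * 10)
}

bench_data <- function(noise = noise_model(0, 0), doses = c(0.1, 10),
                       ions = c("K", "H", "Cl"), step = 20,
                       params = bench_params()) {
  sets <- lapply(seq_along(doses), function(i) {
    nm <- noise_model(noise$relative_sd, noise$floor_sd,
                      seed = noise$seed + i)
    synthesize_fluxes(params, canonical_scenarios(doses[i], step = step)$fit,
                      sample_step = step, noise = nm, ions = ions,
                      condition = sprintf("KCl_%gmM", doses[i]))
  })
  ds <- do.call(rbind, sets)
  structure(ds, sign_convention = "outward_positive",
            provenance = list(source = "synthetic-bench"),
            class = c("flux_dataset", "data.frame"))
}

# A zero-force equilibrium configuration: equal concentrations on both
# sides, no potential, ATP at its reaction equilibrium, all dynamics off.
equilibrium_params <- function() {
  ion_params(
    L = list(HCl = 1e-8, ClCl = 2e-7, NaNa = 1e-9),
    dynamic = list(HH = list(init = 3e-7), KK = list(init = 2e-8)),
    atp = list(C_ATP = 0.3, K = 0, ATP_stimulus = 2.5, k_ATPincr = 0,
               ATP0 = 0.3),
    init = list(pH_in = 5.5, H_out = ph_to_mM(5.5), K_in = 1, K_out = 1,
                Na_in = 1, Na_out = 1, Cl_in = 1, Cl_out = 1,
                delta_phi = 0),
    name = "equilibrium")
}
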