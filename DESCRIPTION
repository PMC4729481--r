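Package: ionNET
Title: Non-Equilibrium Thermodynamic Modelling of Plasma-Membrane Ion Fluxes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, estimation and analysis of coupled H+/K+/Na+/Cl-
    fluxes across the yeast plasma membrane using linear non-equilibrium
    thermodynamics (Onsager phenomenological coefficients). Implements the
    electrochemical force-flux system with ATP-driven active transport,
    proton buffering and membrane-potential dynamics; event-driven stimulus
    scenarios (KCl and glucose additions); multistart particle-swarm fitting
    of phenomenological coefficients to microelectrode ion flux (MIFE-style)
    net-flux time series; flux decompositions by ion and by chemical versus
    electrical potential; and a synthetic flux-data generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, graphics, jsonlite, stats, utils, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
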