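# Parameter set P1 (model variant M1, includes ATP-driven K+ import L_KAr).
# Units as in P2a.yaml.
name: P1
variant: M1
global:
  V_in: 1.8e-11
  V_out: 2.85e-6
  T: 296
  Surf: 2.29e-5
  pbc: 200
  cf: 1000
  K: 0.01136
  C_ATP: 0.07255
  delta_phi: 0.0742
initial:
  H_out: 3.162e-3
  K_out: 0.1
  Cl_out: 0.1
  ATP: 2.303
  ATP_stimulus: 2.5
  pH_in: 5.528
  K_in: 90.39
  Cl_in: 8.217
  Na_in: 5.778
  Na_out: 0.0863
coefficients:
  L_HHinit: 2.64e-8
  L_HHaG: 2.68e-8
  L_HNa: -1.03e-8
  L_HAraG: 4.09e-10
  L_HCl: 1.33e-9
  L_KKinit: 4.05e-22
  L_KKaG: 2.91e-4
  L_KAraG: -1.26e-4
  L_NaNa: 8.74e-9
  L_ClCl: 3.49e-7
  k_incrHH: 3.51e-7
  k_incrHAr: 2.39e-9
  k_incrKK: 5.15e-9
  k_incrKAr: -9.93e-10
  k_ATPincr: 0.0991
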