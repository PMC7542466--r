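# Physical-transport-only configuration (no biological uptake)
parameters:
  F_T: 0.260
  F_R: 0.033
  F_B: 0.0
  F_A: 0.0
  k_P: 1.0
  psi_MP: 0.0
  R_F_MP: 1.0
run:
  years: [1950, 2020]
  spinup_years: 30
  dt_days: 0.5
columns:
  - name: tropics
    surface_C: 28
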