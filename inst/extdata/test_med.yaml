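# Moderate surface-concentration sample parameterisation (TestMed)
parameters:
  F_T: 0.276
  F_R: 0.011
  F_B: 0.528
  F_A: 0.092
  k_P: 615.508
  psi_MP: 0.193
  R_F_MP: 0.993
run:
  years: [1950, 2020]
  spinup_years: 30
  dt_days: 0.5
columns:
  - name: tropics
    surface_C: 28
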