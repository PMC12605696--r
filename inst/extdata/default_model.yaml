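model:
  F: 0.96        # oral bioavailability
  ka: 1.9        # absorption rate constant (1/h), fixed
  theta_V: 34.3  # typical volume of distribution (L)
  theta_CL: 0.38 # typical clearance (L/h)
  omega_V: 0.71  # IIV SD on V (lognormal)
  omega_CL: 0.4  # IIV SD on CL
  gamma_CL: 0.36 # IOV SD on CL
  sigma_prop: 0.082 # proportional residual SD
  exp_V: 1.0     # allometric exponent on V
  exp_CL: 0.75   # allometric exponent on CL
  med_IBW: 68.8  # centering ideal body weight (kg)
  tlag: 0.0
simulation:
  target_lower: 18    # mg/L
  target_upper: 40
  toxic: 70
  schedule_h: 12
  ibw_grid: [55, 60, 65, 70, 75, 80]
  loading_grid: {from: 100, to: 2500, by: 100}
  maintenance_grid: {from: 50, to: 500, by: 50}
  loading_eval_h: 12
  maintenance_eval_h: 336
  iov_window_h: 48
  infusion_duration_h: 0.0833333333
  n_sim_loading: 100000
  n_sim_maintenance: 10000
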