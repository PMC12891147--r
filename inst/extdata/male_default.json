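{
  "sex": "male",
  "n_subjects": 2000,
  "age_mean": 72.3, "age_sd": 4.5, "age_min": 65,
  "fn_t_mean": -1.065, "fn_t_sd": 1.0,
  "ls_t_mean": -1.004, "ls_t_sd": 1.2,
  "t_frailty_loading": 0.7,
  "olvf_rate_base": 0.28, "olvf_rate_frailty_slope": 0.85,
  "severity_probs": [0.45, 0.25, 0.15, 0.055, 0.05, 0.045],
  "fx_intercept": -5.748, "fx_frailty_slope": 1.696,
  "death_rate": 0.0605,
  "horizon_years": 5,
  "seed": 1
}
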