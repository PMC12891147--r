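{
  "sex": "female",
  "n_subjects": 2000,
  "age_mean": 72.5, "age_sd": 4.5, "age_min": 65,
  "fn_t_mean": -1.734, "fn_t_sd": 1.0,
  "ls_t_mean": -2.325, "ls_t_sd": 1.3,
  "t_frailty_loading": 0.7,
  "olvf_rate_base": 0.195, "olvf_rate_frailty_slope": 1.1,
  "severity_probs": [0.36, 0.18, 0.11, 0.09, 0.11, 0.15],
  "fx_intercept": -6.614, "fx_frailty_slope": 2.321,
  "death_rate": 0.025,
  "horizon_years": 5,
  "seed": 1
}
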