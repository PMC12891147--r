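{
  "sex": "female",
  "n_subjects": 2000,
  "t_frailty_loading": 0.0,
  "olvf_rate_frailty_slope": 0.0,
  "fx_intercept": -4.305, "fx_frailty_slope": 0.0,
  "horizon_years": 5,
  "seed": 1
}
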