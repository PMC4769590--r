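{
  "label": "rat-4000",
  "growth": {
    "v0_cm3": 0.0157,
    "td0_days": 1.35,
    "theta": 0.838
  },
  "radio": {
    "alpha": 0.145,
    "alpha_beta": 10,
    "t_star": 1,
    "t_m": 10
  },
  "treatment": {
    "dose_gy": 40,
    "t_r_days": 11,
    "tau_rad_days": 8,
    "t_cl_days": 4
  },
  "meta": {
    "series": "rat-rhabdomyosarcoma",
    "n_obs": 14
  }
}
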