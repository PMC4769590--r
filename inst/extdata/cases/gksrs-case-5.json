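{
  "label": "gksrs-case-5",
  "growth": {
    "v0_cm3": 0.101,
    "td0_days": 7.8,
    "theta": 0.99
  },
  "radio": {
    "alpha": 0.05,
    "alpha_beta": 10,
    "t_star": 1,
    "t_m": 10
  },
  "treatment": {
    "dose_gy": 24.3,
    "t_r_days": 29,
    "tau_rad_days": 8,
    "t_cl_days": 20
  },
  "td_at_treatment_days": 7.9,
  "meta": {
    "series": "gksrs",
    "local_control": "PD"
  }
}
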