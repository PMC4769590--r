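{
  "label": "gksrs-case-4",
  "growth": {
    "v0_cm3": 0.031,
    "td0_days": 6.6,
    "theta": 0.78
  },
  "radio": {
    "alpha": 0.1,
    "alpha_beta": 10,
    "t_star": 1,
    "t_m": 10
  },
  "treatment": {
    "dose_gy": 22,
    "t_r_days": 78,
    "tau_rad_days": 8,
    "t_cl_days": 10
  },
  "td_at_treatment_days": 16.1,
  "meta": {
    "series": "gksrs",
    "local_control": "SD",
    "t_r_alt_days": 8
  }
}
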