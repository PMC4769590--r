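{
  "label": "gksrs-case-2",
  "growth": {
    "v0_cm3": 0.0065,
    "td0_days": 6,
    "theta": 0.77
  },
  "radio": {
    "alpha": 0.19,
    "alpha_beta": 10,
    "t_star": 1,
    "t_m": 10
  },
  "treatment": {
    "dose_gy": 21.2,
    "t_r_days": 117,
    "tau_rad_days": 8,
    "t_cl_days": 38
  },
  "td_at_treatment_days": 28,
  "meta": {
    "series": "gksrs",
    "local_control": "PR"
  }
}
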