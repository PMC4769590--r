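{
  "label": "gksrs-case-1",
  "growth": {
    "v0_cm3": 0.126,
    "td0_days": 29,
    "theta": 0.62
  },
  "radio": {
    "alpha": 0.09,
    "alpha_beta": 10,
    "t_star": 1,
    "t_m": 10
  },
  "treatment": {
    "dose_gy": 38.3,
    "t_r_days": 34,
    "tau_rad_days": 8,
    "t_cl_days": 13
  },
  "td_at_treatment_days": 32.6,
  "meta": {
    "series": "gksrs",
    "local_control": "CR"
  }
}
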