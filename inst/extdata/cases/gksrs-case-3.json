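{
  "label": "gksrs-case-3",
  "growth": {
    "v0_cm3": 0.271,
    "td0_days": 9,
    "theta": 0.53
  },
  "radio": {
    "alpha": 0.19,
    "alpha_beta": 10,
    "t_star": 1,
    "t_m": 10
  },
  "treatment": {
    "dose_gy": 26,
    "t_r_days": 22,
    "tau_rad_days": 8,
    "t_cl_days": 40
  },
  "td_at_treatment_days": 11.2,
  "meta": {
    "series": "gksrs",
    "local_control": "PR",
    "t_r_alt_days": 137
  }
}
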