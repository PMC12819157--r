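{
  "name": "dc_gater",
  "pore": "../pores/wt_like.json",
  "rate_model": {"polarity": "negative", "critical_voltage": 0.1,
                 "closing_prefactor": 1, "closing_efold_voltage": 0.04,
                 "opening_rate": 50, "reopening_window": 0.15},
  "closed_state": {"mean_ratio": 0.14, "sd_ratio": 0.05},
  "n_pores": 1,
  "protocol": {"kind": "constant", "baseline": -0.16, "duration": 4,
               "sample_rate": 5000},
  "noise_sd": 2e-12,
  "seed": 1
}
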