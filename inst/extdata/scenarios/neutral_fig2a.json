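{
  "name": "neutral_fig2a",
  "pore": "../pores/neutral.json",
  "rate_model": {"polarity": "none", "critical_voltage": 0.1,
                 "closing_prefactor": 0, "closing_efold_voltage": 0.04,
                 "opening_rate": 0, "reopening_window": 0.15},
  "closed_state": {"mean_ratio": 0.14, "sd_ratio": 0.05},
  "n_pores": 6,
  "protocol": {"kind": "fig2a", "sample_rate": 10000, "duration": 0.5},
  "noise_sd": 2e-12,
  "seed": 7
}
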