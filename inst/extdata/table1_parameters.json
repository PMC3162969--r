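[
  {"name": "nonaligned_0.03", "group": "nonaligned", "GP_pct": 0.03,
   "C10_kPa": 11.0, "k1_kPa": 21000, "k2": 600, "gamma_deg": 45.0, "kappa": 0.333},
  {"name": "nonaligned_0.1", "group": "nonaligned", "GP_pct": 0.1,
   "C10_kPa": 16.5, "k1_kPa": 29750, "k2": 850, "gamma_deg": 45.0, "kappa": 0.333},
  {"name": "nonaligned_0.25", "group": "nonaligned", "GP_pct": 0.25,
   "C10_kPa": 17.0, "k1_kPa": 40250, "k2": 1150, "gamma_deg": 45.0, "kappa": 0.333},
  {"name": "aligned_0.03", "group": "aligned", "GP_pct": 0.03,
   "C10_kPa": 11.0, "k1_kPa": 5950, "k2": 170, "gamma_deg": 20.0, "kappa": 0.321},
  {"name": "aligned_0.1", "group": "aligned", "GP_pct": 0.1,
   "C10_kPa": 16.5, "k1_kPa": 10500, "k2": 300, "gamma_deg": 29.0, "kappa": 0.323},
  {"name": "aligned_0.25", "group": "aligned", "GP_pct": 0.25,
   "C10_kPa": 17.0, "k1_kPa": 11200, "k2": 320, "gamma_deg": 22.5, "kappa": 0.322}
]
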