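{
  "model": {
    "genome_length_bp": 16569,
    "copy_number": { "kind": "log10_uniform", "lower": 2, "upper": 4 },
    "polg_error_rate": { "kind": "uniform", "lower": 2.8e-8, "upper": 5.6e-7 },
    "x1": { "kind": "uniform", "lower": 10, "upper": 80 },
    "x2": { "kind": "uniform", "lower": 180, "upper": 380 },
    "x3": { "kind": "uniform", "lower": 81, "upper": 101 },
    "proliferating": true,
    "halving_factor": 2,
    "age_years": 70
  },
  "turnover": {
    "half_life_days": 91.3125,
    "hsc_cycle_weeks": 40,
    "days_per_year": 365.25,
    "weeks_per_year": 52.18
  },
  "simulation": {
    "n_samples": 1000000,
    "seed": 1
  },
  "drift": [
    { "h0": 0.05, "advantage": 0.20, "n_rounds": 45,  "convention": "halved" },
    { "h0": 0.01, "advantage": 0.02, "n_rounds": 280, "convention": "halved" },
    { "h0": 0.10, "advantage": 0.02, "n_rounds": 280, "convention": "halved" },
    { "h0": 0.01, "advantage": 0.05, "n_rounds": 280, "convention": "halved" },
    { "h0": 0.01, "advantage": 0.02, "n_rounds": 371, "convention": "halved" }
  ]
}
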