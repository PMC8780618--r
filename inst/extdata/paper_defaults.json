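{
  "seed": 1,
  "morphometrics": {
    "k_max": 5,
    "alpha": 0.05,
    "n_boot": 500,
    "bandwidth_rule": "silverman"
  },
  "demography": {
    "age_origin": "adult_emergence",
    "female_fraction": 0.5,
    "r_method": "birch",
    "ci": "jackknife"
  },
  "synthetic": {
    "n_instars": 3,
    "base_width": 248.14,
    "dyar_ratio": [1.5447, 1.4694],
    "cv": 0.06,
    "class_weights": [0.2959, 0.2653, 0.4388],
    "n": 98,
    "n_females": 20,
    "daily_fecundity_mean": 5.85,
    "egg_viability": 0.552,
    "female_fraction": 0.5
  }
}
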