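[
  {
    "name": "synthetic_logistic_a",
    "comment": "SYNTHETIC placeholder equation (maternal factors + UtA-PI + PAPP-A). Not published coefficients: edit this file to plug in a published model.",
    "intercept": -4.0,
    "terms": {
      "weight_c": 0.012,
      "smoker": 0.55,
      "chronic_htn": 0.9,
      "nulliparous": 0.35,
      "log10mom_utapi": 3.2,
      "log10mom_pappa": -1.3
    }
  },
  {
    "name": "synthetic_logistic_b",
    "comment": "SYNTHETIC placeholder equation (maternal factors + PAPP-A only).",
    "intercept": -3.8,
    "terms": {
      "age_c": 0.02,
      "weight_c": 0.010,
      "smoker": 0.6,
      "prev_sga": 1.1,
      "log10mom_pappa": -1.6
    }
  },
  {
    "name": "synthetic_logistic_c",
    "comment": "SYNTHETIC placeholder equation (maternal factors + UtA-PI + PAPP-A + MAP MoM).",
    "intercept": -4.2,
    "terms": {
      "weight_c": 0.011,
      "smoker": 0.5,
      "conception_ivf": 0.4,
      "log10mom_utapi": 2.8,
      "log10mom_pappa": -1.2,
      "log10mom_map": 4.0
    }
  }
]
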