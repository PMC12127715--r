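{
  "prior": {
    "mean_g": 39.6798734551,
    "mean_z": 0.2951358093,
    "sd_g": 1.3728273928,
    "sd_z": 0.6673626088,
    "rho": 0.0233240197,
    "effects_g": {
      "nulliparous": 0,
      "smoker": -0.17901306438,
      "chronic_htn": -6.44447031768,
      "diabetes": -1.7901306438,
      "sle_aps": -7.51854870396,
      "conception_oi": -0.53703919314,
      "conception_ivf": -0.8950653219,
      "prev_pe": -3.93828741636,
      "prev_sga": -0.53703919314,
      "prev_stillbirth": -5.3703919314
    },
    "effects_z": {
      "nulliparous": -0.69418471722,
      "smoker": -1.20872207904207,
      "chronic_htn": -1.8629118123145,
      "diabetes": 1.3336837424993,
      "sle_aps": -2.40479202010692,
      "conception_oi": -0.155242651026208,
      "conception_ivf": -0.258737751710347,
      "prev_pe": 0.712713138394471,
      "prev_sga": -2.35349425555621,
      "prev_stillbirth": -1.78382141600208
    }
  },
  "likelihood_planes": {
    "utapi": {
      "biomarker": "utapi",
      "slope_g": -0.03,
      "slope_z": -0.065,
      "sigma": 0.12,
      "g0": 37,
      "z0": -1.2
    },
    "pappa": {
      "biomarker": "pappa",
      "slope_g": 0.018,
      "slope_z": 0.06,
      "sigma": 0.26,
      "g0": 37,
      "z0": -1
    },
    "plgf": {
      "biomarker": "plgf",
      "slope_g": 0.045,
      "slope_z": 0.05,
      "sigma": 0.16,
      "g0": 37,
      "z0": -1
    }
  },
  "mom_regressions": {
    "utapi": {
      "biomarker": "utapi",
      "reference_log10": 0.230448921378274,
      "terms": [
        {
          "covariate": "ga_at_screen",
          "center": 12,
          "coef": -0.022
        },
        {
          "covariate": "weight",
          "center": 69,
          "coef": -0.0015
        },
        {
          "covariate": "race",
          "level": "Black",
          "coef": 0.02
        },
        {
          "covariate": "smoker",
          "coef": -0.01
        }
      ]
    },
    "pappa": {
      "biomarker": "pappa",
      "reference_log10": 0.477121254719662,
      "terms": [
        {
          "covariate": "ga_at_screen",
          "center": 12,
          "coef": 0.11
        },
        {
          "covariate": "weight",
          "center": 69,
          "coef": -0.008
        },
        {
          "covariate": "race",
          "level": "Black",
          "coef": 0.18
        },
        {
          "covariate": "race",
          "level": "South Asian",
          "coef": -0.05
        },
        {
          "covariate": "race",
          "level": "East Asian",
          "coef": 0.07
        },
        {
          "covariate": "smoker",
          "coef": -0.08
        },
        {
          "covariate": "conception",
          "level": "ivf",
          "coef": -0.12
        },
        {
          "covariate": "conception",
          "level": "ovulation_induction",
          "coef": -0.05
        },
        {
          "covariate": "diabetes",
          "coef": -0.06
        }
      ]
    },
    "plgf": {
      "biomarker": "plgf",
      "reference_log10": 1.57978359661681,
      "terms": [
        {
          "covariate": "ga_at_screen",
          "center": 12,
          "coef": 0.09
        },
        {
          "covariate": "weight",
          "center": 69,
          "coef": -0.004
        },
        {
          "covariate": "race",
          "level": "Black",
          "coef": 0.16
        },
        {
          "covariate": "smoker",
          "coef": 0.13
        },
        {
          "covariate": "conception",
          "level": "ivf",
          "coef": -0.05
        },
        {
          "covariate": "diabetes",
          "coef": -0.03
        }
      ]
    }
  },
  "grid": {
    "g_range": [24, 43],
    "z_range": [-5, 5],
    "g_step": 0.05,
    "z_step": 0.02
  },
  "chart": {
    "mean_coef": [2.43512462072, 0.148305633748, 0.0022043993466, -5.83453414631e-05],
    "sd_coef": [0.201, -0.0015],
    "ga_support": [24, 43]
  }
}
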