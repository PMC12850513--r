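{
  "model": {
    "cycle_length_years": 0.25,
    "horizon_cycles": 12,
    "annual_discount_rate": 0.045,
    "initial_distribution": {"mild": 0.0, "moderate": 0.12, "severe": 0.88},
    "wtp_krw": 30500000,
    "krw_per_usd": 1144.61,
    "mild_handling_mode": "direct",
    "cycle_correction": "half_cycle",
    "discount_timing": "cycle_start"
  },
  "transitions": {
    "PPT": {
      "mild_row_interval_cycles": 2,
      "rows": {
        "mild":     [0.731, 0.268, 0.001],
        "moderate": [0.472, 0.334, 0.194],
        "severe":   [0.612, 0.321, 0.067]
      },
      "alphas": {
        "mild":     [20.995, 7.686, 0.022],
        "moderate": [2.614, 1.618, 1.034],
        "severe":   [22.413, 11.299, 3.048]
      }
    },
    "PT": {
      "mild_row_interval_cycles": 2,
      "rows": {
        "mild":     [0.731, 0.268, 0.001],
        "moderate": [0.052, 0.765, 0.183],
        "severe":   [0.209, 0.569, 0.222]
      },
      "alphas": {
        "mild":     [20.995, 7.686, 0.022],
        "moderate": [0.125, 3.198, 0.954],
        "severe":   [6.572, 20.097, 13.346]
      }
    }
  },
  "costs": {
    "PPT": {
      "medical_components": {
        "consultation": 80.01,
        "syndrome_differentiation": 17.42,
        "ppt_therapy": 201.34
      },
      "transport": 4.32,
      "time": 183.83,
      "time_se": 12.15
    },
    "PT": {
      "consultation": 107.53,
      "scenarios": {
        "costs": [43.83, 47.23, 61.40, 64.80],
        "weights": [0.25, 0.61, 0.08, 0.06],
        "beta": [
          [62183, 186549],
          [151727, 97005],
          [19899, 228833],
          [14924, 233808]
        ]
      },
      "transport": 5.46,
      "time": 209.40,
      "time_se": 14.14
    }
  },
  "productivity_loss": {
    "per_cycle": {"mild": 1645.46, "moderate": 2585.98, "severe": 3405.16},
    "se": {"mild": 123.74, "moderate": 92.96, "severe": 108.29}
  },
  "utility": {
    "by_state": {"mild": 0.837, "moderate": 0.782, "severe": 0.750},
    "qaly_beta": {
      "mild":     [3009.990, 11377.064],
      "moderate": [3738.664, 15392.143],
      "severe":   [2683.764, 11641.459]
    }
  },
  "dsa": {
    "discount_rate_range": [0.035, 0.06],
    "horizon_years_range": [1, 5],
    "initial_moderate_delta": 0.03,
    "medical_cost_fraction": 0.10,
    "transport_delta": {"PPT": 0.43, "PT": 0.55},
    "time_delta": {"PPT": 12.15, "PT": 14.14},
    "productivity_delta": {"mild": 123.74, "moderate": 92.96, "severe": 108.29},
    "qaly_delta": 0.003,
    "transition_delta": {
      "PPT": {
        "mild":     [0.081, 0.081, 0.010],
        "moderate": [0.195, 0.195, 0.157],
        "severe":   [0.079, 0.078, 0.037]
      },
      "PT": {
        "moderate": [0.121, 0.186, 0.155],
        "severe":   [0.071, 0.082, 0.053]
      }
    }
  },
  "psa": {
    "n_iterations": 1000,
    "seed": 20260113,
    "transport_se_fraction": 0.10,
    "wtp_grid": {"from": 0, "to": 60000, "by": 500}
  },
  "trial": {
    "n_per_arm": 50,
    "baseline_distribution": {"moderate": 0.12, "severe": 0.88},
    "utility_sd": 0.1,
    "seed": 1
  }
}
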