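{
  "name": "general_cvd_30yr_synthetic",
  "description": "SYNTHETIC 30-year table: covariate betas of the published 10-year general-CVD model with baseline survival extrapolated under a constant-hazard assumption, S0(30) = S0(10)^3. Not a published competing-risk 30-year model; used only for the 30-year eligibility branch.",
  "horizon_years": 30,
  "synthetic": true,
  "supported_ranges": {"age": [20, 60], "total_chol": [100, 405], "hdl_chol": [10, 100], "systolic_bp": [90, 200]},
  "sex": {
    "female": {
      "baseline_survival": 0.857684,
      "mean_lp": 26.1931,
      "terms": [
        {"name": "age", "transform": "log", "beta": 2.32888},
        {"name": "total_chol", "transform": "log", "beta": 1.20904},
        {"name": "hdl_chol", "transform": "log", "beta": -0.70833},
        {"name": "systolic_bp", "transform": "log", "beta": 2.76157, "when": "bp_untreated"},
        {"name": "systolic_bp", "transform": "log", "beta": 2.82263, "when": "bp_treated"},
        {"name": "smoker", "transform": "identity", "beta": 0.52873},
        {"name": "diabetes", "transform": "identity", "beta": 0.69154}
      ]
    },
    "male": {
      "baseline_survival": 0.703452,
      "mean_lp": 23.9802,
      "terms": [
        {"name": "age", "transform": "log", "beta": 3.06117},
        {"name": "total_chol", "transform": "log", "beta": 1.12370},
        {"name": "hdl_chol", "transform": "log", "beta": -0.93263},
        {"name": "systolic_bp", "transform": "log", "beta": 1.93303, "when": "bp_untreated"},
        {"name": "systolic_bp", "transform": "log", "beta": 1.99881, "when": "bp_treated"},
        {"name": "smoker", "transform": "identity", "beta": 0.65451},
        {"name": "diabetes", "transform": "identity", "beta": 0.57367}
      ]
    }
  }
}
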