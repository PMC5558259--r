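{
  "name": "general_cvd_10yr",
  "description": "Sex-specific Cox model for 10-year risk of a first general cardiovascular event (log-transformed continuous covariates). Risk = 1 - S0 ^ exp(LP - mean_lp).",
  "horizon_years": 10,
  "synthetic": false,
  "supported_ranges": {"age": [30, 74], "total_chol": [100, 405], "hdl_chol": [10, 100], "systolic_bp": [90, 200]},
  "sex": {
    "female": {
      "baseline_survival": 0.95012,
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
      "baseline_survival": 0.88936,
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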