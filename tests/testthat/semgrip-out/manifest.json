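{
  "config": {
    "seed": 1,
    "synth": {
      "channels": 2,
      "duration_s": 3,
      "rest_s": 1,
      "force_levels": [100, 80, 60, 40],
      "gamma": 1.5,
      "noise_floor": 0.02,
      "powerline_amp": 0,
      "n_sessions": 2
    },
    "filter": {
      "low": 20,
      "high": 490,
      "order": 4,
      "rate": 1000
    },
    "windowing": {
      "window_ms": 256,
      "step_ms": 56,
      "entropy_bins": 64
    },
    "split": {
      "train_fraction": 0.7
    },
    "space": {
      "n_estimators": [10, 500],
      "min_samples_leaf": [1, 20]
    },
    "bes": {
      "pop_size": 10,
      "max_iter": 30
    }
  },
  "config_hash": "fe2ebe55fbcdb861ef96538a75d84573",
  "seed": 1,
  "package_version": "0.1.0",
  "r_version": "R version 4.3.3 (2024-02-29)",
  "timestamp": "2026-09-27T16:17:45+0000"
}
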