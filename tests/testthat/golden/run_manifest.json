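{
  "package": "calcitrack",
  "version": "0.1.0",
  "timestamp": "2026-09-19T03:00:07+0000",
  "seed": 42,
  "config": {
    "seed": 42,
    "aggregation": "fov",
    "simulate": {
      "cohort": "wt",
      "n_neurons": 20,
      "n_sessions": 3,
      "frames_per_session": 3000,
      "frame_rate_hz": 10,
      "n_fov": 1,
      "volumes": true,
      "shared_event_rate_per_min": 1,
      "shared_participation_p": 0.2,
      "rate_drift_sd": 1
    },
    "processing": {
      "neuropil_factor": 0.7,
      "cutoff_hz": 5,
      "window_s": 50,
      "pct": 8,
      "short_window_s": 1,
      "band_pct": 60
    },
    "detection": {
      "smooth_frames": 5,
      "k_sd": 3,
      "duration_frames": 10,
      "min_distance_frames": 15
    },
    "binarize": {
      "smooth_frames": 20,
      "k_sd": 2
    },
    "behavior": {
      "min_duration_s": 0.33,
      "w_min_s": 1,
      "w_max_s": 2
    },
    "correlation": {
      "min_frames": 100,
      "n_shuffles": 10
    },
    "dynamics": {
      "n_shuffles": 100,
      "n_boot": 500
    },
    "plaque": {
      "cutoff_um": 40,
      "bin_edges_um": [0, 20, 40, 60, 1000000]
    }
  },
  "counts": {
    "n_neurons": 20,
    "n_sessions": 3,
    "n_events": 772
  }
}
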