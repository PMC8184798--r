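{
  "seed": 42,
  "out_dir": "icshapemap_demo",
  "simulate": {
    "enabled": true,
    "n_transcripts": 6,
    "stem_len": 15,
    "loop_len": 9,
    "mod_rate_ss": 0.02,
    "mod_rate_ds": 0.002,
    "background_rate": 0.002,
    "depth": 400,
    "n_count_transcripts": 30,
    "count_total": 100000,
    "helix_bp": 22,
    "n_models": 10,
    "model_jitter_sd": 0.5
  },
  "params": {
    "min_coverage": 200,
    "cutoffs": [50, 100, 200]
  }
}
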