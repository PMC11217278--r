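{
  "structures": ["SNc"],
  "mesh_params": {"SNc": {"threshold": 0.3, "upsample_pct": 200, "decimate_fraction": 0}},
  "min_count": 10,
  "tie_policy": "lowest",
  "n_seeds_per_vertex": 50,
  "correction": "bonferroni",
  "family_size": 96,
  "seed": 1
}
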