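{
  "simulation": {
    "n_genotypes": 30,
    "n_genotyped": 26,
    "n_loci": 8,
    "n_cuttings": 3,
    "n_reps": 2,
    "blocks_per_rep": 6,
    "traits": ["DIG"],
    "missing_marker_rate": 0.05
  },
  "call_rate_min": 0.85,
  "maf_min": 0.01,
  "blend_weight": 0.95,
  "fdr_q": 0.02,
  "fdr_alpha": 0.05,
  "lrt_alpha": 0.05,
  "out_dir": "ssrgblup_run",
  "seed": 11,
  "reml": { "method": "ai", "tol": 1e-5 }
}
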