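{
  "synthetic": {
    "n_sites": 5000,
    "n_panel": 325,
    "n_neg": 12,
    "n_pos": 18,
    "n_ref": 3,
    "n_genes": 600,
    "n_deg": 50,
    "n_coupled_genes": 15
  },
  "thresholds": {
    "beta_methylated": 0.4,
    "cimp_cutoff": 0.4,
    "dm_delta": 0.4,
    "lfc": 1.0,
    "fdr": 0.05
  },
  "seed": 7,
  "outdir": "results"
}
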