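# Example self-contained run configuration (scaled down for a quick demo).
# Any field of default_run_config() can be set here; omitted fields keep
# their defaults (112 tips, 86 sites, 999 null permutations, ...).
mode: simulate
outdir: commphylo_demo
master_seed: 1
n_null: 199
n_splits: 50
n_trees: 100
top_k: 3
table2_vars: [NRI, SR_plant, ALT_range, MAT]
simulation:
  n_tips: 30
  n_sites: 30
  n_posterior: 60
  subsample: 30
  assembly_alpha: -2
  sar_lambda: 0.4
  beta_vector:
    SR_plant: 0.5
    ALT_range: 0.3
  noise_sd: 0.3
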