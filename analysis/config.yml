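# run configuration for the analysis drivers
seed: 20260921
out_dir: results
simulate:
  n_basins: 6
  sites_per_basin: 20
  n_leaves: 64
  mean_edge_length_km: 6
  n_species: 200
prepare:
  ratio_threshold: 2
  correlation_threshold: 0.27
fit:
  chains: 4
  warmup: 1000
  sampling: 2000
  boundary: squeeze
checks:
  prior_draws: 1000
  retro_replicates: 200
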