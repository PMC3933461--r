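# Demo configuration: end-to-end run on synthetic data with a planted
# 10-gene hotspot. Completes in well under a minute on one CPU.
seed: 1
outdir: expmods_demo_out
synthetic:
  enabled: true
  n_genes: 300
  n_case: 7
  n_control: 5
  effect_size: 4
  noise_sd: 1
  baseline_mean: 8
  n_nodes: 300
  topology: pa
  attachment: 2
  planted_module_size: 10
  planted_internal_density: 0.9
  concordant_frac: 0.8
preprocess:
  enabled: false
diffexp:
  prior_df: ~
hotspot:
  n_seeds: 20
  gamma: 0.5
  min_module_size: 10
  n_perm: 1000
  alpha: 0.05
  adjust: bonferroni
  dedup_jaccard: 0.5
downstream:
  alpha: 0.05
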