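# Default end-to-end pipeline configuration (see ?pipeline_config).
# CLI flags and function arguments override these values.
seed: 1
cohort:
  n_intra: 8
  n_extra: 8
  volume_shape: [16, 24, 24]
  voxel_spacing: [3, 1, 1]
  texture_effect: 1.5
  n_genes: 600
  n_de_genes: 20
  log2fc: 2
  nb_dispersion: 0.1
  n_gene_sets: 20
  set_size: 25
test_cohort:
  n_intra: 6
  n_extra: 6
grid:
  bin_exponents: [3]
  kernels: [1]
  angles: [0, 90]
  families: [first_order, glcm, glrlm]
selection:
  k_target: 8
  alpha: 0.05
  r_threshold: 0.95
model:
  family: NB
  cap: 8
  folds: 5
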