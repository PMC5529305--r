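# Example experiment configuration: a small, fast comparison run.
# Any field of experiment_config() may appear here.
n_patients: 10
seed: 42
n_bins: 64
expand_voxels: 5
fraction: 0.40
lesion_diameter_range_mm: [15.0, 45.0]
icc_n_boot: 100
survival_driver: fo_entropy
survival_coeff: -0.7
flab:
  max_iter: 100
  tol: 1.0e-4
  spatial_weight: 0.5
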