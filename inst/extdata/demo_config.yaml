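seed: 1.0
chrom_length_bp: 1.2e+08
bin_size_bp: 100000.0
pearson_bin_factor: 2.0
regimes:
- WT_Xi
- SMCHD1_KO
n_segments: 25.0
read_depth: 2000000.0
megadomain_boundary_bp: 7.3e+07
mask_quantile: 0.14
min_run_bins: 3.0
span_threshold_bp: 1.0e+07
coverage:
  enrichment_S1: 0.5
  noise_sd: 0.2
counts:
  n_genes: 100.0
  reactivation_fold: 5.0
  dispersion: 0.1
reactivation:
  fold: 3.0
  p_cutoff: 0.1
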