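# Demonstration configuration: simulate a trade-off cohort and run the
# full analysis chain on it. Usage:
#   Rscript inst/scripts/longprs-pipeline.R --config inst/extdata/demo_config.yaml --out demo_run
schema_version: 1
build: hg19
seed: 42
simulate:
  n_individuals: 600
  n_blocks: 400
  n_snps_per_block: 1
  within_block_r: 0.0
  maf_range: [0.2, 0.4]
  architecture: tradeoff
  n_strong: 120
  n_weak: 220
parameters:
  r2_threshold: 0.1
  window_kb: 500
  alpha: 0.05
  hwe_p_min: 1.0e-5
  max_missing: 0.05
  min_maf: 0.01
  cv_k: 5
  cv_iterations: 2
  cv_families: [logistic]
mask_region:
  chrom: "1"
  start: 1
  end: 2000000
stages: [simulate, qc, harmonize, scan, bins, mask, dissect, predict]
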