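# Demonstration pipeline configuration: a 50-gene synthetic cohort with
# planted decay and abundance effects. Run with
#   asdecay run --config demo_config.yaml --out demo_run
simulate:
  n_genes: 50
  fraction_asd: 0.2
  delta_lambda_values: [-0.3, 0.3]
  fraction_asa: 0.2
  asa_log2_offsets: [-1.5, 1.5]
  depth_per_snp: 200
n_boot: 1000
n_perm: 50
fdr_grid: [0.0, 0.02, 0.04, 0.06, 0.08, 0.1]
seed: 20
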