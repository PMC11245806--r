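# Demo configuration: a small simulated co-sequencing study that runs end to
# end in about a minute on one CPU. All sizes are deliberately modest; see
# the package vignette for the full-scale study conditions.
rng_seed: 7
simulate:
  enabled: true
  n_genomes: 8
  n_samples_low: 2
  n_samples_high: 2
  n_shotgun_pairs: 1500
  n_amplicon_reads: 400
  error_rate: 0.002
  amplicon_error_rate: 0
seeds:
  identity: 0.99
  n_samples: 2
  top_k: 300
recruit:
  min_identity: 98
  max_matches: 3
assemble:
  min_cov: 3
  min_report_len: 800
evaluate:
  enabled: true
paths:
  outdir: seedrecon_demo
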