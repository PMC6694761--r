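# Demo run: a small barcoded-library-of-targets experiment end to end.
guide:
  name: demo
  spacer: GGTGAGTGAGTGTGTGCGTGT
  pam: TTGAAT
  cut_offset: 3
simulate:
  n_templates: 250
  per_base_mismatch_rate: 0.10
  copies: 25
  copies_dist: poisson
  replicates: 2
  spikein_copies: 4
  on_target_prob: 0.9
  mean_pcr_duplicates: 2
  error_rate: 0.001
process:
  q_threshold: 20
  min_uncut: 3
quant:
  j: 1
  k: 4
model:
  enabled: true
  hidden: 10
  min_rows: 50
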