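# 3-month RNA-seq structure: 1547 predicted seed-site targets among 12000
# genes; 2583 significantly upregulated and 2381 downregulated genes, of
# which 312 / 311 are targets.
name: cohort3
rng_seed: 20518
transcriptome:
  n_genes: 12000
  n_target_genes: 1547
  n_up_sig: 2583
  n_down_sig: 2381
  n_up_targets: 312
  n_down_targets: 311
  utr_len: 300
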