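# 7-day perilesional cortex qPCR effects: miR-124-3p downregulation
# (target/reference = miR-124-3p/miR-378) and Stat3 upregulation
# (target/reference = Stat3/Gapdh), plus the miR-124-3p vs Stat3
# rank-correlation structure.
name: cohort1_7d
rng_seed: 20418
qpcr:
  mir124:
    planted_fc: 0.13
    n_case: 6
    n_control: 6
    ct_sd: 0.3
    reference_ct_mean: 20
    baseline_dct: 3
    case_label: TBI
    control_label: sham
  stat3:
    planted_fc: 6.97
    n_case: 6
    n_control: 6
    ct_sd: 0.3
    reference_ct_mean: 18
    baseline_dct: 6
    case_label: TBI
    control_label: sham
correlation:
  planted_rho: -0.647
  n_pairs: 24
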