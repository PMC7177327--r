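# Negative control: no layer effect, no group effect, no planted qPCR
# fold change. Every downstream contrast should be non-significant at
# the nominal level most of the time.
name: "null"
rng_seed: 20718
image_geom:
  width_um: 600
  depth_um: 600
  microns_per_pixel: 3
  background_gray: 0.9
  pixel_noise_sd: 0.01
groups:
  - {group_label: naive, n_subjects: 2}
  - {group_label: sham, n_subjects: 2}
  - {group_label: TBI, n_subjects: 2}
layer_effect: 1.0
group_scale:
  naive: 1.0
  sham: 1.0
  TBI: 1.0
signal_mean: 0.25
signal_noise_sd: 0.2
n_cells_per_subject: 60
cell_radius_um: 8
gray_threshold: 0.85
qpcr:
  mir124:
    planted_fc: 1.0
    n_case: 6
    n_control: 6
    ct_sd: 0.3
    reference_ct_mean: 20
    baseline_dct: 3
    case_label: TBI
    control_label: sham
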