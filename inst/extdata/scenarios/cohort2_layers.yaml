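# 7-day in situ hybridization layer structure: deep/superficial intensity
# fold-change 1.9 in naive animals, sham at 71% and TBI at 47% of the
# naive mean per-cell intensity.
name: cohort2_layers
rng_seed: 20318
image_geom:
  width_um: 1000
  depth_um: 1000
  microns_per_pixel: 2
  background_gray: 0.9
  pixel_noise_sd: 0.01
groups:
  - {group_label: naive, n_subjects: 3}
  - {group_label: sham, n_subjects: 3}
  - {group_label: TBI, n_subjects: 3}
layer_effect: 1.9
group_scale:
  naive: 1.0
  sham: 0.71
  TBI: 0.47
signal_mean: 0.25
signal_noise_sd: 0.2
n_cells_per_subject: 400
cell_radius_um: 8
gray_threshold: 0.86
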