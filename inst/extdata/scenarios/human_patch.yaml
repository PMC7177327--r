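# Human temporal-lobe sections: signal inside the patchy neuronal-loss
# area has a lower mean and a wider per-cell spread than outside, with
# comparable cell density.
name: human_patch
rng_seed: 20618
image_geom:
  width_um: 1000
  depth_um: 1000
  microns_per_pixel: 2
  background_gray: 0.9
  pixel_noise_sd: 0.01
groups:
  - {group_label: inside, n_subjects: 1}
  - {group_label: outside, n_subjects: 1}
layer_effect: 1.0
group_scale:
  inside: 0.55
  outside: 1.0
group_noise_sd:
  inside: 0.45
  outside: 0.2
signal_mean: 0.3
signal_noise_sd: 0.2
n_cells_per_subject: 150
cell_radius_um: 8
gray_threshold: 0.85
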