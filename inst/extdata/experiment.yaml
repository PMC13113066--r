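# Example experiment configuration for a desk-scale factor study.
n_boars: 60
prevalence: 0.2336    # ~25/107
image_size: 96
n_runs: 10
base_seed: 1
threshold: 0.3
lambda: 0.01

generator:
  collections_mean: 30
  collections_sd: 9
  shift_high: 6
  shift_under: -6

augmentation:
  group: comprehensive
  p_morphological: 0.5
  p_brightness: 0.5
  magnitudes:
    rotation: 15
    zoom_max: 1.5
    posterize_bits: 4
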