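# Mature primary fibril seeding layer on bare gold (~150 h incubation):
# population means 8.3 +/- 0.85 nm diameter, 842 +/- 133.5 nm length, plus
# a minor population of primary oligomers adsorbed directly on the gold.
description: primary fibril seeding layer, large-area survey frames
frames: 9
field_nm: 2200
pixel_size_nm: 2
time_min: 0
primary_fibrils:
  count: 12
  diameter_mean_nm: 8.3
  diameter_sd_nm: 0.85
  length_mean_nm: 842
  length_sd_nm: 133.5
  persistence_nm: 6000
  rq_range_nm: [0.4, 2.2]
oligomers:
  count: 8
  diameter_mean_nm: 7.3
  diameter_sd_nm: 1.9
  p_edge: 0
  p_backbone: 0
  p_substrate: 1
tip:
  shape: paraboloid
  radius_nm: 2
artifacts:
  line_offset_sigma_nm: 1.0
  tilt_nm_per_um: [2, 2]
  pixel_noise_sigma_nm: 0.15
substrate_sigma_nm: 0.15
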