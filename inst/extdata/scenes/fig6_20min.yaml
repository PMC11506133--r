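# ~20 min time point: secondary oligomers have grown to 11.9 +/- 0.3 nm
# and adsorb along the primary fibril backbones as well as the edges.
description: 20-minute oligomer growth stage
frames: 5
field_nm: 2000
pixel_size_nm: 2
time_min: 20
primary_fibrils:
  count: 7
  diameter_mean_nm: 8.3
  diameter_sd_nm: 0.85
  length_mean_nm: 842
  length_sd_nm: 133.5
  rq_range_nm: [0.4, 2.2]
oligomers:
  count: 18
  diameter_mean_nm: 11.9
  diameter_sd_nm: 0.3
  p_edge: 0.3
  p_backbone: 0.7
  p_substrate: 0
tip:
  shape: paraboloid
  radius_nm: 2
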