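# Catalytic-activity scene: one designated high-activity primary fibril
# (hotspot) receives eight-fold the cargo of its neighbours; some fibrils
# stay bare (dormant).
description: dormant / active / superspreader classification
frames: 2
field_nm: 2200
pixel_size_nm: 2
time_min: 60
primary_fibrils:
  count: 8
  diameter_mean_nm: 8.3
  diameter_sd_nm: 0.85
  length_mean_nm: 842
  length_sd_nm: 133.5
  rq_range_nm: [0.4, 2.2]
oligomers:
  count: 16
  diameter_mean_nm: 7.9
  diameter_sd_nm: 0.2
  p_edge: 0.4
  p_backbone: 0.6
  p_substrate: 0
hotspot:
  index: 1
  factor: 8
tip:
  shape: paraboloid
  radius_nm: 2
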