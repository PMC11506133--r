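# Embryonic adsorption-site scene (~30 s): secondary oligomers strongly
# prefer fibril edges over the backbone on first contact.
description: edge-preference adsorption site classification
frames: 3
field_nm: 2000
pixel_size_nm: 2
time_min: 0.5
primary_fibrils:
  count: 8
  diameter_mean_nm: 8.3
  diameter_sd_nm: 0.85
  length_mean_nm: 842
  length_sd_nm: 133.5
  rq_range_nm: [0.4, 2.2]
oligomers:
  count: 20
  diameter_mean_nm: 7.9
  diameter_sd_nm: 0.2
  p_edge: 0.8
  p_backbone: 0.2
  p_substrate: 0
tip:
  shape: paraboloid
  radius_nm: 2
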