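# Late growth phase (~180 min): long secondary fibrils (2200 +/- 145 nm)
# lying on the substrate among the primary seeding fibrils, distinguished
# from primaries by their higher surface corrugation.
description: growth-phase secondary fibril elongation
frames: 5
field_nm: 4200
pixel_size_nm: 2
time_min: 180
primary_fibrils:
  count: 3
  diameter_mean_nm: 8.3
  diameter_sd_nm: 0.85
  length_mean_nm: 842
  length_sd_nm: 133.5
  rq_range_nm: [0.4, 2.2]
secondary_fibrils:
  count: 5
  stacked_on_primary: false
  diameter_mean_nm: 6.9
  diameter_sd_nm: 0.5
  length_mean_nm: 2200
  length_sd_nm: 145
  persistence_nm: 20000
  rq_range_nm: [2.5, 8.5]
  rq_shape: [1.4, 4.6]
tip:
  shape: paraboloid
  radius_nm: 2
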