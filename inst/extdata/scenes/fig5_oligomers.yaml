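# Embryonic secondary nucleation (~10 min after depositing the oligomer
# solution): secondary oligomers on the fibril layer (7.9 +/- 0.2 nm),
# primary oligomers on bare gold (7.3 +/- 1.9 nm), and the first stacked
# secondary fibrils (250 +/- 55 nm long, 6.5 +/- 0.2 nm diameter) riding
# on primary fibrils.
description: embryonic-phase oligomer sizing and stacked-height subtraction
frames: 6
field_nm: 2000
pixel_size_nm: 2
time_min: 10
primary_fibrils:
  count: 8
  diameter_mean_nm: 8.3
  diameter_sd_nm: 0.85
  length_mean_nm: 842
  length_sd_nm: 133.5
  rq_range_nm: [0.4, 2.2]
secondary_fibrils:
  count: 4
  stacked_on_primary: true
  diameter_mean_nm: 6.5
  diameter_sd_nm: 0.2
  length_mean_nm: 250
  length_sd_nm: 55
  rq_range_nm: [2.5, 3.0]
oligomers:
  - count: 16
    diameter_mean_nm: 7.9
    diameter_sd_nm: 0.2
    p_edge: 0.5
    p_backbone: 0.5
    p_substrate: 0
  - count: 22
    diameter_mean_nm: 7.3
    diameter_sd_nm: 1.9
    p_edge: 0
    p_backbone: 0
    p_substrate: 1
tip:
  shape: paraboloid
  radius_nm: 2
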