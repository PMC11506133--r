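# Two-class roughness fingerprinting scene: smooth primaries (Rq 0.4--2.2
# nm) and corrugated secondaries (Rq spanning 2.5--8.5 nm, right-skewed so
# the mean Rq ratio is the observed ~threefold), all lying on the
# substrate.
description: backbone Rq fingerprinting of fibril generations
frames: 8
field_nm: 3000
pixel_size_nm: 2
time_min: 240
primary_fibrils:
  count: 6
  diameter_mean_nm: 8.3
  diameter_sd_nm: 0.85
  length_mean_nm: 800
  length_sd_nm: 150
  rq_range_nm: [0.4, 2.2]
secondary_fibrils:
  count: 7
  stacked_on_primary: false
  diameter_mean_nm: 6.5
  diameter_sd_nm: 0.6
  length_mean_nm: 900
  length_sd_nm: 180
  rq_range_nm: [2.5, 8.5]
  rq_shape: [1.4, 4.6]
tip:
  shape: paraboloid
  radius_nm: 2
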