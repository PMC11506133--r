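test_that("flattening removes exactly what it models", {
  # zero image stays zero
  z <- heightmap(matrix(0, 64, 64), 2)
  fl <- flatten(z)
  expect_equal(fl$map$heights, z$heights, tolerance = 1e-12)
  expect_equal(unname(fl$report$row_offsets_nm), rep(0, 64))

  # pure per-row offsets, no objects, order 0: exact removal
  set.seed(41)
  off <- rnorm(64)
  hm <- heightmap(matrix(off, 64, 64), 2)   # recycled down columns = per row
  fl0 <- flatten(hm, order = 0)
  expect_lt(max(abs(fl0$map$heights)), 1e-9)
})

test_that("flattening recovers substrate and apex on a simulated frame", {
  # tilt and line offsets but no pixel noise: flattening must restore the
  # substrate to ~0 and leave the fibril apex within 0.2 nm of truth
  spec <- scene_spec(field_nm = 1200, pixel_size_nm = 2, seed = 42,
    primary_fibrils = list(count = 1, diameter_sd_nm = 0, rq_range_nm = c(0, 0),
                           length_mean_nm = 600, length_sd_nm = 0),
    artifacts = list(line_offset_sigma_nm = 1, tilt_nm_per_um = c(3, 2),
                     pixel_noise_sigma_nm = 0),
    substrate_sigma_nm = 0)
  sim <- simulate_topograph(spec)
  fl <- flatten(sim$map)
  sub <- fl$map$heights[fl$map$heights < 1.0]
  expect_lt(abs(stats::median(sub)), 0.05)
  expect_equal(max(fl$map$heights), 8.3, tolerance = 0.2)
})

test_that("flattening is idempotent and offset-invariant", {
  spec <- small_primary_spec(43, n_fib = 3, n_olig = 2)
  sim <- simulate_topograph(spec)
  f1 <- flatten(sim$map)$map
  f2 <- flatten(f1)$map
  expect_lt(sqrt(mean((f2$heights - f1$heights)^2)), 1e-3)

  # adding a constant then re-flattening with order 0 restores the baseline
  shifted <- set_heights <- f1
  shifted$heights <- f1$heights + 3.7
  f3 <- flatten(shifted, order = 0)$map
  b1 <- substrate_baseline(f1)
  b3 <- substrate_baseline(f3)
  expect_equal(b1, b3, tolerance = 1e-6)
})

test_that("substrate baseline contracts hold", {
  spec <- small_primary_spec(44, n_fib = 2, n_olig = 0)
  sim <- simulate_topograph(spec)
  fl <- flatten(sim$map)$map
  expect_lt(abs(substrate_baseline(fl)), 0.05)

  # fully covered field: no bare substrate -> informative error
  tall <- heightmap(matrix(10, 32, 32) + rnorm(1024, sd = 0.05), 2)
  expect_error(substrate_baseline(tall, mask = matrix(TRUE, 32, 32)),
               "bare substrate")
})

test_that("starved scanlines fall back to the global fit and are reported", {
  set.seed(45)
  h <- matrix(rnorm(64 * 64, sd = 0.1), 64, 64)
  h[10, 1:58] <- 200           # a row that is almost entirely "object"
  fl <- flatten(heightmap(h, 2), order = 0, iterations = 2)
  expect_true(10 %in% fl$report$fallback_rows)
  expect_gte(fl$report$masked_fraction, 0)
})
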