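test_that("ideal surface realizes height-equals-diameter exactly", {
  # axis-aligned fibril on a pixel row: apex equals the configured diameter
  hm <- render_objects(c(800, 400), 2,
    fibrils = list(list(poly = cbind(c(100, 700), c(200, 200)),
                        diameter_nm = 8.3)))
  expect_equal(max(hm$heights), 8.3)
  # a lone sphere: apex = diameter, footprint radius = d/2
  hm2 <- render_objects(c(200, 200), 1,
    oligomers = list(list(x = 100, y = 100, diameter_nm = 8)))
  expect_equal(max(hm2$heights), 8)
  footprint <- which(hm2$heights > 0, arr.ind = TRUE)
  expect_lte(max(abs(footprint[, 2] - 1 - 100)), 4)
  expect_gte(sum(hm2$heights[101, ] > 0), 7)  # ~9 px across at 1 nm/px
})

test_that("objects compose by upper envelope: oligomer atop fibril", {
  hm <- render_objects(c(400, 400), 2,
    fibrils = list(list(poly = cbind(c(50, 350), c(200, 200)),
                        diameter_nm = 8)),
    oligomers = list(list(x = 200, y = 200, diameter_nm = 6,
                          support_nm = 8)))
  expect_equal(max(hm$heights), 14)                       # 8 + 6
  expect_equal(hm$heights[101, 101], 14)                  # at the centre
})

test_that("scene generation is bit-identical for a fixed seed", {
  spec <- small_primary_spec(77, n_fib = 3, n_olig = 3)
  a <- simulate_topograph(spec)
  b <- simulate_topograph(spec)
  expect_identical(a$map$heights, b$map$heights)
  expect_identical(a$truth$objects, b$truth$objects)
})

test_that("placement class sampling follows the configured probabilities", {
  set.seed(31)
  cls <- sample_placement_classes(10000, 0.7, 0.2, 0.1)
  expect_equal(mean(cls == "edge"), 0.7, tolerance = 0.02)
  expect_equal(mean(cls == "backbone"), 0.2, tolerance = 0.02)
})

test_that("degenerate placement probabilities behave as contracted", {
  # p_substrate = 1: no hosts recorded
  spec <- small_primary_spec(32, n_fib = 2, n_olig = 6)
  sc <- render_scene(spec)
  ol <- sc$truth$objects[sc$truth$objects$class == "oligomer", ]
  expect_true(all(is.na(ol$host_id)))
  expect_true(all(ol$placement == "substrate"))

  # p_edge = 1: every oligomer within the 20 nm edge window of an endpoint
  spec2 <- scene_spec(field_nm = 2000, pixel_size_nm = 2, seed = 33,
    primary_fibrils = list(count = 4),
    oligomers = list(count = 8, diameter_mean_nm = 7.9, diameter_sd_nm = 0.2,
                     p_edge = 1, p_backbone = 0, p_substrate = 0))
  sc2 <- render_scene(spec2)
  xy <- sc2$truth$oligomer_xy
  obj <- sc2$truth$objects
  for (k in seq_len(nrow(xy))) {
    host <- obj$host_id[obj$id == xy$id[k]]
    L <- obj$true_length_nm[obj$id == host]
    expect_lte(min(xy$arc_nm[k], L - xy$arc_nm[k]), 20)
  }

  # on-fibril probabilities with zero fibrils must error
  spec3 <- scene_spec(field_nm = 1000, pixel_size_nm = 2, seed = 34,
    primary_fibrils = list(count = 0),
    oligomers = list(count = 2, p_edge = 1, p_backbone = 0, p_substrate = 0))
  expect_error(render_scene(spec3), "no primary fibrils")
})

test_that("on-backbone oligomer spacing respects the 20 nm minimum", {
  spec <- scene_spec(field_nm = 2000, pixel_size_nm = 2, seed = 35,
    primary_fibrils = list(count = 2),
    oligomers = list(count = 14, diameter_mean_nm = 7.9, diameter_sd_nm = 0.2,
                     p_edge = 0, p_backbone = 1, p_substrate = 0))
  sc <- render_scene(spec)
  xy <- sc$truth$oligomer_xy
  hosts <- sc$truth$objects$host_id[match(xy$id, sc$truth$objects$id)]
  for (h in unique(hosts)) {
    arcs <- sort(xy$arc_nm[hosts == h])
    if (length(arcs) > 1) expect_gte(min(diff(arcs)), 20)
  }
})

test_that("corrugation calibration realizes the requested Rq exactly", {
  set.seed(36)
  for (target in c(0.8, 2.2, 2.5, 5, 8.5)) {
    c0 <- afmtrace:::gen_corrugation(800, 1, 50, target, 6.5)
    expect_equal(windowed_rq(6.5 + c0, 1, 100)$rq_nm, target,
                 tolerance = 1e-6)
    expect_gte(min(6.5 + c0), 3)      # local diameter never below 3 nm
  }
  # ground-truth Rq recorded in the scene equals the realized profile Rq
  spec <- scene_spec(field_nm = 2500, pixel_size_nm = 2, seed = 37,
    primary_fibrils = list(count = 3))
  sc <- render_scene(spec)
  rqs <- sc$truth$objects$true_rq_nm
  expect_true(all(rqs >= 0.4 - 1e-6 & rqs <= 2.2 + 1e-6))
})

test_that("scan artifacts are reproducible and calibrated", {
  spec <- scene_spec(field_nm = c(256, 1024), pixel_size_nm = 2, seed = 38,
    primary_fibrils = list(count = 0),
    artifacts = list(line_offset_sigma_nm = 1, tilt_nm_per_um = c(0, 0),
                     pixel_noise_sigma_nm = 0),
    substrate_sigma_nm = 0)
  hm <- heightmap(matrix(0, 513, 129), 2)
  a <- add_scan_artifacts(hm, spec)
  b <- add_scan_artifacts(hm, spec)
  expect_identical(a$heights, b$heights)          # same seed, same output
  # per-row medians of the added offsets have SD ~ 1 nm over 513 rows
  offsets <- apply(a$heights - hm$heights, 1, stats::median)
  expect_equal(stats::sd(offsets), 1, tolerance = 0.1)

  # all sigmas zero and no tilt: identity
  spec0 <- scene_spec(field_nm = 256, pixel_size_nm = 2, seed = 39,
    primary_fibrils = list(count = 0),
    artifacts = list(line_offset_sigma_nm = 0, tilt_nm_per_um = c(0, 0),
                     pixel_noise_sigma_nm = 0),
    substrate_sigma_nm = 0)
  expect_identical(add_scan_artifacts(hm, spec0)$heights, hm$heights)
})

test_that("impossible scenes fail with an informative error", {
  spec <- scene_spec(field_nm = 300, pixel_size_nm = 2, seed = 40,
    primary_fibrils = list(count = 12))   # 842 nm fibrils cannot fit
  expect_error(render_scene(spec), "could not place")
})
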