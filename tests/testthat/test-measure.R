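test_that("a lone sphere on the substrate measures its diameter", {
  hm <- render_objects(c(300, 300), 2,
    oligomers = list(list(x = 150, y = 150, diameter_nm = 8)))
  g <- apply_tip(hm, tip_model("paraboloid", 2))
  pm <- measure_particle(c(150, 150), g, support_nm = 0)
  expect_equal(pm$diameter_nm, 8, tolerance = 0.1)
  expect_identical(pm$n_sections, 5L)
})

test_that("stacked-object subtraction recovers the upper object's size", {
  hm <- render_objects(c(600, 400), 2,
    fibrils = list(list(poly = cbind(c(50, 550), c(200, 200)),
                        diameter_nm = 8)),
    oligomers = list(list(x = 300, y = 200, diameter_nm = 6, support_nm = 8)))
  g <- apply_tip(hm, tip_model("paraboloid", 2))
  an <- analyze_topograph(g)
  r <- an$records
  ol <- r[r$class == "oligomer", ]
  expect_identical(nrow(ol), 1L)
  expect_equal(ol$diameter_nm, 6, tolerance = 0.2)
  # total apex is fibril + oligomer; support is the fibril height
  fl <- flatten(g)$map
  pm <- measure_particle(c(300, 200), fl,
                         support_nm = subtract_support(c(300, 200), an$traces))
  expect_equal(pm$mean_apex_nm, 14, tolerance = 0.2)
  expect_equal(pm$support_nm, 8, tolerance = 0.3)
})

test_that("secondary fibrils riding a primary are decomposed correctly", {
  spec <- scene_spec(field_nm = 2000, pixel_size_nm = 2, seed = 61,
    primary_fibrils = list(count = 6),
    secondary_fibrils = list(count = 3, stacked_on_primary = TRUE,
                             rq_range_nm = c(2.5, 3.0)))
  sim <- simulate_topograph(spec)
  an <- analyze_topograph(sim$map)
  sec <- an$records[an$records$class == "secondary_fibril", ]
  expect_identical(nrow(sec), 3L)
  expect_true(all(!is.na(sec$host_id)))
  ts <- sim$truth$objects[sim$truth$objects$class == "secondary_fibril", ]
  expect_equal(mean(sec$length_nm), mean(ts$true_length_nm), tolerance = 25)
  expect_equal(mean(sec$diameter_nm), mean(ts$true_diameter_nm),
               tolerance = 0.5)
  # supports sit at the host apex (~8.3 nm primaries)
  for (k in seq_len(nrow(sec))) {
    host_d <- an$records$diameter_nm[an$records$object_id == sec$host_id[k]]
    expect_equal(host_d, 8.3, tolerance = 2.5)  # population spread
  }
})

test_that("host resolution breaks ties deterministically toward lower ids", {
  tr1 <- straight_trace(y = 100)
  tr2 <- straight_trace(y = 120)
  traces <- list(f02 = tr2, f01 = tr1)   # intentionally unsorted
  res <- resolve_host(c(450, 110), traces)  # equidistant from both
  expect_identical(res$host_id, "f01")
  expect_true(res$tie_flag)
  # far object: no host, substrate support
  far <- resolve_host(c(450, 400), traces, max_dist_nm = 50)
  expect_identical(far$host_id, NA_character_)
  expect_identical(subtract_support(c(450, 400), traces, max_dist_nm = 50), 0)
})

test_that("profile decomposition finds runs and bumps, not corrugation", {
  set.seed(62)
  n <- 500; spacing <- 2
  s <- (seq_len(n) - 1) * spacing
  corr <- 2 * sin(2 * pi * s / 50)                  # Rq ~ 1.4: primary-like
  apex <- 8.3 + corr + rnorm(n, sd = 0.1)
  apex[200:260] <- apex[200:260] + 6.5              # 120 nm stacked run
  bump <- exp(-((s - 700) / 5)^2) * 8               # one 8 nm particle
  apex <- apex + bump
  pb <- afmtrace:::profile_bumps(apex, spacing)
  expect_identical(nrow(pb$runs), 1L)
  expect_lt(abs(pb$runs$from - 200), 8)
  expect_lt(abs(pb$runs$to - 260), 8)
  expect_identical(nrow(pb$bumps), 1L)
  expect_lt(abs(pb$bumps$index - 351), 4)           # s = 700 -> index 351
  # pure corrugation yields neither runs nor bumps
  pb0 <- afmtrace:::profile_bumps(8.3 + corr, spacing)
  expect_identical(nrow(pb0$runs), 0L)
  expect_identical(nrow(pb0$bumps), 0L)
})
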