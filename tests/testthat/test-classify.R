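test_that("site classification follows the geometric contract", {
  tr <- straight_trace(length_nm = 800, y = 100)  # backbone x in [50, 850]
  traces <- list(f01 = tr)
  # far from any backbone: substrate
  expect_identical(
    classify_site(c(450, 300), traces)$site, "substrate")
  # 5 nm (arc) from an endpoint, on the backbone: edge
  expect_identical(classify_site(c(55, 100), traces)$site, "edge")
  expect_identical(classify_site(c(845, 100), traces)$site, "edge")
  # mid-backbone: backbone
  expect_identical(classify_site(c(450, 102), traces)$site, "backbone")
  # just outside the on-fibril gate: substrate
  expect_identical(classify_site(c(450, 100 + 12), traces)$site, "substrate")
})

test_that("Rq obeys its closed forms and invariances", {
  s <- seq(0, 999, by = 1)
  # constant profile: zero roughness
  expect_equal(windowed_rq(rep(5, 500), 1)$rq_nm, 0)
  # sinusoid with integer periods per window: Rq = A / sqrt(2) exactly
  # under per-window mean removal; the default linear detrend additionally
  # absorbs the component of the sinusoid collinear with a ramp (a ~8%
  # effect at 2 periods/window), so it is checked against the closed form
  # with a 10% band
  z <- 1.0 * sin(2 * pi * s / 50)
  expect_equal(windowed_rq(z, 1, 100, detrend = "constant")$rq_nm,
               1 / sqrt(2), tolerance = 1e-9)
  expect_equal(windowed_rq(z, 1, window_nm = 100)$rq_nm, 1 / sqrt(2),
               tolerance = 0.1)
  # invariant to constants and linear ramps (detrending)
  expect_equal(windowed_rq(z + 7, 1, 100)$rq_nm,
               windowed_rq(z, 1, 100)$rq_nm, tolerance = 1e-9)
  expect_equal(windowed_rq(z + 0.05 * s, 1, 100)$rq_nm,
               windowed_rq(z, 1, 100)$rq_nm, tolerance = 1e-2)
  # scales linearly with amplitude
  expect_equal(windowed_rq(3 * z, 1, 100)$rq_nm,
               3 * windowed_rq(z, 1, 100)$rq_nm, tolerance = 1e-9)
  # lower-sided Rq equals two-sided (mean-removed) for a symmetric profile
  expect_equal(windowed_rq(z, 1, 100, side = "lower")$rq_nm,
               windowed_rq(z, 1, 100, detrend = "constant")$rq_nm,
               tolerance = 0.02)
  # ... but ignores sparse upward cargo entirely
  cargo <- z + 8 * (s %% 100 < 8)
  expect_equal(windowed_rq(cargo, 1, 100, side = "lower")$rq_nm,
               windowed_rq(z, 1, 100, detrend = "constant")$rq_nm,
               tolerance = 0.06)
})

test_that("rq_roughness windows traces and flags short ones", {
  tr <- straight_trace(length_nm = 800, apex = 8.3)
  tr$apex_nm <- tr$apex_nm + 1.0 * sin(2 * pi * seq_along(tr$apex_nm) * 2 / 50)
  rec <- rq_roughness(tr, window_nm = 100)
  expect_s3_class(rec, "roughness_record")
  expect_identical(rec$n_windows, 8L)
  expect_false(rec$short_flag)
  short <- straight_trace(length_nm = 60)
  expect_true(rq_roughness(short)$short_flag)
})

test_that("generation threshold is monotone with an inclusive boundary", {
  expect_identical(classify_generation(1.0), "primary")
  expect_identical(classify_generation(5.0), "secondary")
  expect_identical(classify_generation(2.35), "secondary")  # boundary up
  expect_identical(classify_generation(2.349999), "primary")
  rqs <- seq(0.2, 8, by = 0.2)
  cls <- classify_generation(rqs)
  expect_true(all(diff(cls == "secondary") >= 0))           # monotone
})

test_that("activity classification implements the lambda rule", {
  lengths <- stats::setNames(rep(1000, 4), c("f1", "f2", "f3", "f4"))
  counts <- stats::setNames(c(1L, 1L, 1L, 4L), names(lengths))
  act <- classify_activity(counts, lengths)
  expect_identical(act$activity, c("active", "active", "active",
                                   "superspreader"))
  # zero attachments: dormant, and dormant <=> count == 0
  counts0 <- stats::setNames(c(0L, 2L, 2L, 2L), names(lengths))
  act0 <- classify_activity(counts0, lengths)
  expect_identical(act0$activity[1], "dormant")
  expect_true(all((act0$count == 0) == (act0$activity == "dormant")))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  act_p <- classify_activity(counts[perm], lengths[perm])
  expect_identical(act_p, act)
  # fewer than 3 non-dormant fibrils: superspreader rule inert
  lengths2 <- stats::setNames(rep(1000, 3), c("f1", "f2", "f3"))
  counts2 <- stats::setNames(c(0L, 1L, 9L), names(lengths2))
  act2 <- classify_activity(counts2, lengths2)
  expect_false("superspreader" %in% act2$activity)
})

test_that("a designated hotspot fibril is recovered as a superspreader", {
  st <- run_scene_study(scene_file("fig6_activity.yaml"), seed = 63,
                        frames = 1, keep_truth = TRUE)
  an <- st$analyses[[1]]
  expect_true("superspreader" %in% an$activity$activity)
  # the superspreader is the most heavily loaded fibril
  ss <- an$activity[an$activity$activity == "superspreader", ]
  expect_identical(max(an$activity$count), max(ss$count))
})

test_that("site distributions normalize correctly and report absences", {
  sd1 <- site_distribution(c(rep("edge", 8), rep("backbone", 2)))
  expect_equal(unname(sd1$on_fibril_fractions), c(0.8, 0.2))
  expect_equal(sum(sd1$fractions), 1)
  expect_equal(sd1$norm_area_nm2, 500)
  sd2 <- site_distribution(rep("substrate", 5))
  expect_null(sd2$on_fibril_fractions)
  expect_identical(sd2$counts[["substrate"]], 5L)
})
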