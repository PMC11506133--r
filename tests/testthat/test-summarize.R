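test_that("population summaries use closed-form moments and fixed bins", {
  s1 <- summarize_population(c(8, 8, 8))
  expect_equal(s1$mean, 8); expect_equal(s1$sd, 0); expect_identical(s1$n, 3L)
  s2 <- summarize_population(c(6, 10))
  expect_equal(s2$mean, 8); expect_equal(s2$sd, 2)     # population denominator
  expect_identical(sum(s2$counts), s2$n)               # histogram conserves n
  expect_equal(s2$bin_width_nm, 0.5)
  expect_equal(summarize_population(c(500, 900), "length_nm")$bin_width_nm, 100)
  # order invariance
  set.seed(71)
  v <- rnorm(50, 8, 1)
  expect_equal(summarize_population(v), summarize_population(rev(v)))
  # empty selection is explicit, not an error
  s0 <- summarize_population(numeric(0))
  expect_identical(s0$n, 0L); expect_true(is.na(s0$mean))
})

test_that("growth curves order time points and flag monotonicity", {
  rec <- data.frame(
    frame_id = rep(c("a", "b"), each = 3),
    time_min = rep(c(10, 180), each = 3),
    class = "secondary_fibril",
    length_nm = c(250, 240, 260, 2200, 2150, 2250),
    stringsAsFactors = FALSE)
  gc <- growth_curves(rec, "length_nm")
  tab <- gc$curves$trial1
  expect_equal(tab$time_min, c(10, 180))
  expect_equal(tab$mean, c(250, 2200))
  expect_true(gc$flags$trial1$increasing)
  expect_false(gc$flags$trial1$decreasing)

  # duplicate time within one trial: error
  bad <- rec; bad$time_min <- 10
  expect_error(growth_curves(bad, "length_nm"), "duplicate time_min")

  # independent trials stay separate
  rec$trial <- rep(c("t1", "t2"), 3)
  gc2 <- growth_curves(rec, "length_nm")
  expect_identical(sort(names(gc2$curves)), c("t1", "t2"))
})

test_that("re-writing the same records is byte-identical", {
  spec <- small_primary_spec(72, n_fib = 3, n_olig = 3)
  sim <- simulate_topograph(spec)
  an <- analyze_topograph(sim$map)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "m1.csv"); p2 <- file.path(dir, "m2.csv")
  write_measurements(an$records, p1)
  write_measurements(an$records, p2)
  expect_identical(readLines(p1), readLines(p2))
})
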