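analyze_single_ridge <- function(poly, diameter = 8.3, field = c(800, 400),
                                 px = 2, tip_R = 2, seed = NULL) {
  hm <- render_objects(field, px,
    fibrils = list(list(poly = poly, diameter_nm = diameter)))
  g <- apply_tip(hm, tip_model("paraboloid", tip_R))
  analyze_topograph(g)
}

test_that("a straight ridge measures its endpoint separation", {
  an <- analyze_single_ridge(cbind(c(150, 550), c(150, 150)))
  r <- an$records
  expect_identical(nrow(r), 1L)
  expect_equal(r$length_nm, 400, tolerance = 2)
  expect_equal(r$diameter_nm, 8.3, tolerance = 0.1)
})

test_that("a quarter-circle ridge measures pi * R / 2", {
  theta <- seq(0, pi / 2, length.out = 200)
  poly <- cbind(100 + 200 * cos(theta), 100 + 200 * sin(theta))
  an <- analyze_single_ridge(poly, field = c(500, 500))
  r <- an$records
  expect_identical(nrow(r), 1L)
  expect_equal(r$length_nm, pi * 200 / 2, tolerance = 3)
})

test_that("segmentation separates fibrils from particles and handles blanks", {
  blank <- heightmap(matrix(0, 64, 64), 2)
  expect_warning(seg <- segment_objects(blank), "empty foreground")
  expect_identical(nrow(seg$objects), 0L)

  hm <- render_objects(c(1200, 600), 2,
    fibrils = list(list(poly = cbind(c(100, 942), c(200, 200)),
                        diameter_nm = 8.3)),
    oligomers = list(list(x = 600, y = 450, diameter_nm = 8)))
  g <- apply_tip(hm, tip_model("paraboloid", 2))
  seg <- segment_objects(g)
  expect_identical(sum(seg$objects$type == "fibril"), 1L)
  expect_identical(sum(seg$objects$type == "particle"), 1L)
})

test_that("fibril-only scenes yield no particles", {
  spec <- small_primary_spec(51, n_fib = 6, n_olig = 0)
  sim <- simulate_topograph(spec)
  an <- analyze_topograph(sim$map)
  expect_identical(sum(an$records$class == "oligomer"), 0L)
  expect_identical(sum(an$records$class == "primary_fibril"), 6L)
})

test_that("length and diameter recover ground truth on noisy frames", {
  derr <- c(); lerr <- c()
  for (seed in 52:53) {
    spec <- small_primary_spec(seed, n_fib = 8, n_olig = 0)
    sim <- simulate_topograph(spec)
    an <- analyze_topograph(sim$map)
    m <- match_fibrils(an, sim$truth)
    derr <- c(derr, m$d_meas - m$d_true)
    lerr <- c(lerr, m$L_meas - m$L_true)
  }
  expect_lt(abs(mean(derr)), 0.15)
  expect_lt(abs(mean(lerr)), 8)              # < half a pixel per end + jitter
  expect_lt(max(abs(lerr)), 25)              # ~3% of an 842 nm fibril
})

test_that("short components are demoted to particles", {
  hm <- render_objects(c(300, 300), 2,
    fibrils = list(list(poly = cbind(c(130, 165), c(150, 150)),
                        diameter_nm = 8)))   # 35 nm < 50 nm minimum
  an <- analyze_topograph(hm)
  expect_identical(sum(an$records$class %in%
                       c("primary_fibril", "secondary_fibril")), 0L)
})
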