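test_that("tip dilation matches the brute-force oracle on small grids", {
  set.seed(21)
  for (shape in c("paraboloid", "cone")) {
    tip <- tip_model(shape, radius_nm = 3, half_angle_deg = 20)
    for (rep in 1:4) {
      f <- matrix(rnorm(24 * 28, sd = 3), 24, 28)
      se <- afmtrace:::tip_matrix(tip, pixel_size_nm = 1,
                                  z_range = diff(range(f)))
      expect_equal(grey_dilate_cpp(f, se), dilate_brute(f, se),
                   tolerance = 1e-12)
    }
  }
})

test_that("a single spike dilates to the closed-form paraboloid profile", {
  f <- matrix(0, 32, 32); f[16, 16] <- 10
  g <- apply_tip(heightmap(f, 1), tip_model("paraboloid", radius_nm = 2))
  # g(x) = 10 - x^2 / (2R) around the spike
  expect_equal(g$heights[16, 18], 10 - 2^2 / 4)
  expect_equal(g$heights[16, 17], 10 - 1 / 4)
  expect_equal(max(g$heights), 10)           # apex preserved
})

test_that("dilation is extensive, translation-equivariant, flat-invariant", {
  set.seed(22)
  tip <- tip_model("paraboloid", 2)
  f <- matrix(0, 40, 40)
  f[12:14, 20:22] <- 6
  hm <- heightmap(f, 1)
  g <- apply_tip(hm, tip)
  expect_true(all(g$heights >= f - 1e-12))                 # extensive
  expect_equal(max(g$heights), max(f))                     # max preserved
  flat <- heightmap(matrix(2.5, 32, 32), 1)
  expect_equal(apply_tip(flat, tip)$heights, flat$heights) # flat unchanged
  # translation equivariance (interior feature, shifted by 5 px)
  f2 <- matrix(0, 40, 40); f2[17:19, 25:27] <- 6
  g2 <- apply_tip(heightmap(f2, 1), tip)
  expect_equal(g2$heights[10:25, 15:35], g$heights[5:20, 10:30])
})

test_that("erosion of the dilation brackets the true surface", {
  set.seed(23)
  spec <- small_primary_spec(23, n_fib = 2, n_olig = 2)
  sc <- render_scene(spec)
  tip <- tip_model("paraboloid", 2)
  g <- apply_tip(sc$ideal, tip)
  r <- erode_tip(g, tip)
  expect_true(all(g$heights - r$heights >= -1e-9))   # r <= g
  expect_true(all(r$heights - sc$ideal$heights >= -1e-9))  # f <= r
})

test_that("measured diameter is robust to tip radius (heights, not widths)", {
  ds <- vapply(c(2, 5, 10), function(R) {
    hm <- render_objects(c(800, 300), 2,
      fibrils = list(list(poly = cbind(c(100, 700), c(150, 150)),
                          diameter_nm = 8.3)))
    g <- apply_tip(hm, tip_model("paraboloid", R))
    an <- analyze_topograph(g)
    an$records$diameter_nm[an$records$class == "primary_fibril"]
  }, 0)
  expect_true(all(abs(ds - 8.3) <= 0.3))
  expect_lt(max(ds) - min(ds), 0.3)
})
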