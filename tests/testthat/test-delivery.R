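# Rasterization, the GS/CS frame transform, accumulation, resampling.

test_that("rasterized aperture integral matches the analytic area", {
  g <- grid_spec(0.05, 13.5)
  cp <- single_pair_cp(A = -3, B = 2)
  d <- rasterize_aperture(cp, g)
  # one open pair [-3, 2] x 1 cm band -> 5 cm^2
  expect_equal(sum(d$values) * g$spacing_cm^2, 5.0, tolerance = 1e-9)
  # opening bank A by 0.1 cm adds exactly 0.1 cm^2
  cp2 <- single_pair_cp(A = -3.1, B = 2)
  d2 <- rasterize_aperture(cp2, g)
  expect_equal(sum(d2$values - d$values) * g$spacing_cm^2, 0.1,
               tolerance = 1e-9)
  # blur conserves the integral for an interior aperture
  db <- rasterize_aperture(cp, g, blur_sigma_cm = 0.3)
  expect_equal(sum(db$values) * g$spacing_cm^2, 5.0, tolerance = 1e-6)
  expect_true(all(db$values >= 0))
})

test_that("all-closed apertures rasterize to zero; off-grid apertures error", {
  g <- grid_spec(0.05, 13.5)
  cp <- control_point(1, 0, 1, rep(0, 40), rep(0, 40))
  expect_equal(sum(rasterize_aperture(cp, g)$values), 0)
  # open aperture entirely outside a small grid
  small <- grid_spec(0.05, 1)
  cp2 <- single_pair_cp(A = 5, B = 8, pair = 20)  # band y in [-1, 0]... x off-grid
  expect_error(rasterize_aperture(cp2, small), class = "arcqa_extent_error")
})

test_that("partial-area weighting is exact at cell boundaries", {
  g <- grid_spec(0.1, 1)
  # edge at 0.025 covers a quarter of the cell centered at 0... cell [-0.05, 0.05]
  cp <- single_pair_cp(A = 0.025, B = 0.975, pair = 10, n = 20)
  d <- rasterize_aperture(cp, g, leaf_width_cm = 0.1)
  ax <- grid_axis(g)
  iy <- which(abs(ax + 0.1) < 1e-9)  # cell straddling the band edge
  jx <- which(abs(ax - 0) < 1e-9)
  expect_equal(d$values[iy, jx], 0.25 * 0.5)  # x quarter-cover, y half-cover
})

test_that("frame transform is identity for GS, mirrors CS beyond +/-90", {
  g <- grid_spec(0.05, 13.5)
  cp <- single_pair_cp(A = -3, B = 2)  # asymmetric aperture
  f <- rasterize_aperture(cp, g)
  for (ang in c(-170, -90, 0, 45, 90, 170)) {
    expect_equal(frame_transform(f, ang, "GS")$values, f$values)
  }
  expect_equal(frame_transform(f, 45, "CS")$values, f$values)
  m <- frame_transform(f, 180, "CS")$values
  expect_equal(m, f$values[, ncol(f$values):1])
  expect_false(isTRUE(all.equal(m, f$values)))  # aperture is asymmetric
  # the +/-90 boundary belongs to the flipped branch
  expect_equal(frame_transform(f, 90, "CS")$values, m)
  expect_equal(frame_transform(f, -90, "CS")$values, m)
  expect_error(frame_transform(f, 181, "CS"), class = "arcqa_domain_error")
  # optional deposition weight scales the map
  w <- frame_transform(f, 60, "CS", angle_weight = function(a) 0.5)
  expect_equal(w$values, 0.5 * f$values)
})

test_that("accumulation conserves total fluence between frames", {
  p <- generate_arc_plan(generator_config(seed = 2))
  g <- grid_spec(0.1, 13.5)
  gs <- accumulate_dose(p, "GS", g, list(penumbra_sigma_cm = 0))
  cs <- accumulate_dose(p, "CS", g, list(penumbra_sigma_cm = 0))
  expect_lt(abs(sum(gs$values) - sum(cs$values)) / sum(gs$values), 1e-9)
})

test_that("collapsed-gantry GS and CS accumulations are element-wise identical", {
  p <- collapse_gantry(generate_arc_plan(generator_config(seed = 2)))
  g <- grid_spec(0.1, 13.5)
  gs <- accumulate_dose(p, "GS", g, list(penumbra_sigma_cm = 0))
  cs <- accumulate_dose(p, "CS", g, list(penumbra_sigma_cm = 0))
  expect_identical(gs$values, cs$values)
  expect_equal(gs$delivery_mode, "collapsed")
})

test_that("a symmetric aperture at gantry 0 gives equal, x-symmetric maps", {
  g <- grid_spec(0.1, 13.5)
  cp <- single_pair_cp(A = -2, B = 2)
  p <- arc_plan("sym", list(cp), delivery_mode = "collapsed")
  gs <- accumulate_dose(p, "GS", g, list(penumbra_sigma_cm = 0))
  cs <- accumulate_dose(p, "CS", g, list(penumbra_sigma_cm = 0))
  expect_equal(gs$values, cs$values)
  expect_equal(gs$values, gs$values[, ncol(gs$values):1])
})

test_that("resampling: uniform stays uniform; array preset gives 27x27", {
  g <- grid_spec(0.05, 13.5)
  u <- planar_dose(matrix(2, g$n, g$n), g)
  det <- detector_spec("array729")
  r <- resample_to_detector(u, det)
  expect_equal(dim(r$values), c(27L, 27L))
  expect_true(all(abs(r$values - 2) < 1e-12))
  expect_equal(r$grid$spacing_cm, 1.0)
  # point-sample epid preset keeps the value too
  re <- resample_to_detector(u, detector_spec("epid"))
  expect_true(all(re$values == 2))
})

test_that("area-averaged values bracket a step edge between two elements", {
  g <- grid_spec(0.05, 13.5)
  ax <- grid_axis(g)
  V <- matrix(0, g$n, g$n)
  V[, ax > 0.5 - 1e-9] <- 1  # step exactly between elements at 0 and 1 cm
  d <- planar_dose(V, g)
  r <- resample_to_detector(d, detector_spec("array729"))
  mid <- (27 + 1) / 2
  left <- r$values[mid, mid]       # element centered at 0
  right <- r$values[mid, mid + 1]  # element centered at +1
  expect_lt(left, 0.5)
  expect_gt(right, 0.5)
  # coarse-on-fine area averaging is refused
  coarse <- planar_dose(matrix(1, 28, 28)[1:27, 1:27], grid_spec(1, 13))
  expect_error(
    resample_to_detector(coarse, detector_spec(NULL, 0.3, 0.3, "area-average")),
    class = "arcqa_config_error"
  )
})

test_that("dose CSV round-trips values, grid and tags", {
  p <- tiny_plan()
  g <- grid_spec(0.3, 13.5)
  d <- accumulate_dose(p, "CS", g, list(penumbra_sigma_cm = 0.3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dose_csv(d, f)
  d2 <- read_dose_csv(f)
  expect_equal(d2$values, d$values, tolerance = 1e-7)
  expect_equal(d2$grid$spacing_cm, 0.3)
  expect_equal(d2$frame, "CS")
  expect_equal(d2$delivery_mode, "rotational")
})
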