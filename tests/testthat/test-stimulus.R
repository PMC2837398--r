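# Stimulus geometry and rendering against analytic footprints.

test_that("angular size follows the approach law", {
  # distance equal to the half-length: 90 degrees exactly
  expect_equal(angular_size(0.3, 10, 30), 90)
  # closed forms: 2*atan(1/3) and 2*atan(0.5)
  expect_equal(angular_size(0.1, 10, 30), 2 * atan(1 / 3) * 180 / pi)
  expect_equal(angular_size(0.5, 10, 100), 2 * atan(0.5) * 180 / pi)
  # monotonically increasing as collision nears
  th <- angular_size(0.3, 10, seq(500, 10, -10))
  expect_true(all(diff(th) > 0))
  expect_error(angular_size(0.3, 10, 0), "positive")
  expect_error(angular_size(0.3, 10, -5), "positive")
})

test_that("camera geometry enforces consistency between fov, grid and resolution", {
  g <- camera_geometry()
  expect_equal(g$deg_per_pixel, 2.33)
  expect_equal(g$px_w, g$fov_h / g$grid_w)
  expect_error(camera_geometry(deg_per_pixel = 5), "inconsistent")
})

test_that("sub-pixel objects render as uniform background", {
  g <- test_geom()
  spec <- looming_spec(l = 0.3, v = 10, start_theta = 0.5,
                       t_start = -60000, t_end = -59000)
  fr <- render_frame(spec, g, -60000)
  # theta = 0.5 deg over a 2.33 deg cell: at most a faint smudge
  expect_true(all(fr > 250))
  expect_equal(dim(fr), c(g$grid_h, g$grid_w))
})

test_that("an object larger than the field renders fully dark (solid shapes)", {
  g <- test_geom()
  spec <- looming_spec(l = 0.3, v = 10)
  fr <- render_frame(spec, g, -1)   # theta essentially 180 deg
  expect_true(all(fr < 5))
})

test_that("a 23.3 deg solid square covers exactly a centred 10x10 cell block", {
  g <- test_geom()
  # choose l/|v| and t so theta = 10 * deg_per_pixel: edges land on cell borders
  lov <- 30
  t <- -lov / tan(5 * g$deg_per_pixel * pi / 180)
  spec <- looming_spec(l = 0.3, v = 1000 * 0.3 / lov)
  fr <- render_frame(spec, g, t)
  dark <- fr < 128
  expect_equal(sum(dark), 100)
  expect_true(all(which(rowSums(dark) > 0) == 8:17))
  expect_true(all(which(colSums(dark) > 0) == 12:21))
})

test_that("rendered square footprint width tracks the analytic angular size", {
  g <- test_geom()
  spec <- looming_spec(l = 0.3, v = 10)
  for (t in c(-400, -250, -150, -100, -60)) {
    th <- angular_size(spec$l, spec$v, -t)
    fr <- render_frame(spec, g, t)
    cols <- colSums(fr < 255 / 2) > 0
    expect_lte(abs(sum(cols) - round(th / g$deg_per_pixel)), 1)
  }
})

test_that("angle offset translates the footprint without changing its area", {
  g <- test_geom()
  t <- -150
  areas <- sapply(c(0, 0.1, 0.2, 0.3), function(off) {
    spec <- looming_spec(l = 0.3, v = 10, angle_offset = off)
    sum(255 - render_frame(spec, g, t))   # total darkness = area proxy
  })
  expect_true(max(abs(areas - areas[1])) / areas[1] < 0.01)
  # a large offset starts clipping: area must drop
  spec_far <- looming_spec(l = 0.3, v = 10, angle_offset = 0.95)
  expect_lt(sum(255 - render_frame(spec_far, g, t)), areas[1] * 0.99)
})

test_that("looming sequences grow strictly, receding shrink, expansion is linear", {
  g <- test_geom()
  sq <- render_sequence(looming_spec(l = 0.3, v = 10, start_theta = 5), g)
  motion <- sq$times >= sq$spec$t_start
  expect_true(all(diff(sq$theta[motion]) > 0))
  # frame count matches the window and rate (plus the hold frames)
  expected_n <- floor((sq$spec$t_end - sq$spec$t_start) / sq$dt) + 1 +
    floor(sq$spec$hold_ms / sq$dt)
  expect_lte(abs(dim(sq$frames)[3] - expected_n), 1)

  # receding at 10 m/s from a 30 cm half-length: strictly decreasing
  rc <- render_sequence(looming_spec(mode = "receding", l = 0.3, v = 10,
                                     start_theta = 40), g)
  motion_r <- rc$times > rc$spec$t_start
  expect_true(all(diff(rc$theta[motion_r]) < 0))
  expect_equal(max(rc$theta), 40, tolerance = 1e-9)

  # uniform expansion: exactly linear growth in time
  ux <- render_sequence(looming_spec(mode = "uniform_expansion",
                                     expansion_rate = 0.04, start_theta = 5), g)
  motion_u <- ux$times >= ux$spec$t_start
  dth <- diff(ux$theta[motion_u])
  expect_equal(dth, rep(0.04 * ux$dt, length(dth)), tolerance = 1e-9)
})

test_that("contrast ratio scales the object luminance", {
  g <- test_geom()
  fr_inf <- render_frame(looming_spec(l = 0.3, v = 10), g, -100)
  fr_2 <- render_frame(looming_spec(l = 0.3, v = 10, contrast_ratio = 2), g, -100)
  expect_equal(min(fr_inf), 0)
  expect_equal(min(fr_2), 255 / 2, tolerance = 1)
  # no contrast: uniform frame
  fr_1 <- render_frame(looming_spec(l = 0.3, v = 10, contrast_ratio = 1), g, -100)
  expect_true(all(abs(fr_1 - 255) < 1e-9))
})

test_that("sensor noise is seed-deterministic and distributionally sane", {
  g <- test_geom()
  sq <- short_loom()
  expect_identical(add_sensor_noise(sq, 0, 1), sq)
  n1 <- add_sensor_noise(sq, 5, 123)
  n2 <- add_sensor_noise(sq, 5, 123)
  expect_identical(n1$frames, n2$frames)
  n3 <- add_sensor_noise(sq, 5, 124)
  expect_false(identical(n1$frames, n3$frames))
  # mean shift ~0 and sd ~5 on cells away from clipping
  mid <- sq$frames > 20 & sq$frames < 235
  resid <- (n1$frames - sq$frames)[mid]
  expect_lt(abs(mean(resid)), 3 * 5 / sqrt(length(resid)))
  expect_equal(stats::sd(resid), 5, tolerance = 0.1)
  # noise must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(add_sensor_noise(sq, 5, 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("degenerate stimulus windows and shapes are rejected", {
  expect_error(looming_spec(t_start = -10, t_end = -100), "empty")
  expect_error(looming_spec(t_end = 10), "collision")
  expect_error(looming_spec(contrast_ratio = 0.5))
  g <- test_geom()
  sp <- looming_spec()
  sp$shape <- "hexagon"
  expect_error(render_frame(sp, g, -100), "unknown shape")
})
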