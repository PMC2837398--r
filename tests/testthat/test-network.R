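# Network layers against brute-force oracles, and end-to-end response
# properties of the full model.

test_that("lamina rejects uniform fields and matches a brute-force convolution", {
  cfg <- network_config()
  uniform <- matrix(0.7, 24, 32)
  lam <- lamina_step(uniform, NULL, cfg)
  expect_true(all(abs(lam$output) < 1e-12))

  # dark square on bright ground: activity only within one kernel radius of
  # the border, and steady-state activity equal to the direct double-loop
  # convolution (iterate the leaky layer to its fixed point)
  fr <- matrix(1, 24, 32)
  fr[10:15, 14:19] <- 0
  oracle <- brute_centre_surround(fr, cfg$surround_weight)
  st <- NULL
  for (k in 1:120) { lam2 <- lamina_step(fr, st, cfg); st <- lam2$state }
  ss <- oracle * cfg$lamina$R
  expect_equal(lam2$output, ss * (ss >= cfg$lamina$v_thresh), tolerance = 1e-4)
  border_dist <- matrix(Inf, 24, 32)
  for (r in 1:24) for (c in 1:32) {
    on_border <- (r >= 9 & r <= 16 & c >= 13 & c <= 20) &
                 !(r >= 11 & r <= 14 & c >= 15 & c <= 18)
    if (on_border) border_dist[r, c] <- 0
  }
  expect_true(all(lam2$output[border_dist > 0 &
                              !(matrix(FALSE, 24, 32))] >= 0))
  active <- which(lam2$output > 0, arr.ind = TRUE)
  expect_true(all(active[, 1] >= 9 & active[, 1] <= 16 &
                  active[, 2] >= 13 & active[, 2] <= 20))
})

test_that("inverting the contrast flips the lamina drive sign exactly", {
  cfg <- network_config()
  fr <- matrix(1, 24, 32); fr[8:14, 10:18] <- 0
  inv <- 1 - fr
  d1 <- lgmdsim:::conv3x3(fr, {
    k <- matrix(cfg$surround_weight, 3, 3); k[2, 2] <- 1; k
  }, pad = "replicate")
  d2 <- lgmdsim:::conv3x3(inv, {
    k <- matrix(cfg$surround_weight, 3, 3); k[2, 2] <- 1; k
  }, pad = "replicate")
  expect_equal(d1, -d2, tolerance = 1e-12)
})

test_that("medulla transient detectors respond to change only", {
  cfg <- network_config()
  # static scene: after the front-end membranes settle (tau = 20 ms against
  # 10 ms frames), the transient detectors are silent
  frames <- moving_edge_frames(16, step = 0)
  res <- run_layers(frames, cfg)
  for (k in 13:16) {
    expect_true(all(res[[k]]$on == 0))
    expect_true(all(res[[k]]$off == 0))
  }
  # step appearance of an edge: on-cells respond right after the step
  blank <- matrix(255, 5, 20)
  withedge <- moving_edge_frames(1, from = 8)[[1]]
  app <- run_layers(list(blank, blank, withedge, withedge, withedge), cfg)
  expect_true(sum(app[[3]]$on) > 0)
  expect_true(all(app[[2]]$on == 0))
  # long after the appearance the transients die out
  app2 <- run_layers(c(list(blank, blank), rep(list(withedge), 14)), cfg)
  expect_lt(sum(app2[[16]]$on) + sum(app2[[16]]$off), 1e-6)
})

test_that("a translating edge drives the matching directional ensemble", {
  cfg <- network_config()
  frames <- moving_edge_frames(12, step = 1)
  res <- run_layers(frames, cfg)
  right_total <- sum(sapply(res[5:12], function(x) sum(x$dir$right)))
  left_total <- sum(sapply(res[5:12], function(x) sum(x$dir$left)))
  expect_gt(right_total, 0)
  expect_gt(right_total, 2 * max(left_total, 1e-9))
  # paired off (vacated) and on (entered) activity each frame once moving
  k <- 8
  expect_gt(sum(res[[k]]$on), 0)
  expect_gt(sum(res[[k]]$off), 0)
  on_col <- which(colSums(res[[k]]$on) > 0)
  off_col <- which(colSums(res[[k]]$off) > 0)
  expect_true(min(on_col) > min(off_col))   # onset leads, offset trails
})

test_that("an expanding square drives left and right ensembles symmetrically", {
  cfg <- network_config()
  g <- test_geom()
  sq <- render_sequence(looming_spec(l = 0.3, v = 1000 * 0.3 / 20,
                                     start_theta = 12), g)
  frames <- lapply(seq_len(dim(sq$frames)[3]), function(k) sq$frames[, , k])
  res <- run_layers(frames, cfg)
  right_total <- sum(sapply(res, function(x) sum(x$dir$right)))
  left_total <- sum(sapply(res, function(x) sum(x$dir$left)))
  expect_gt(right_total, 0)
  expect_equal(right_total, left_total, tolerance = 0.05 * right_total)
  # right-edge activity sits in the right half of the grid
  late <- res[[length(res) - 2]]
  if (sum(late$dir$right) > 0) {
    cols <- which(colSums(late$dir$right) > 0)
    expect_true(mean(cols) > 16)
  }
})

test_that("fan-in total activity is maximal when the edges sit at +/- delta", {
  cfg <- network_config(noise_sigma = 0)
  g <- test_geom()
  # brute-force sweep: expanding square passing slowly through all sizes;
  # accumulate fan activity per half-width
  sq <- render_sequence(looming_spec(l = 0.3, v = 1000 * 0.3 / 50,
                                     start_theta = 8, t_end = -20), g)
  frames <- lapply(seq_len(dim(sq$frames)[3]), function(k) sq$frames[, , k])
  res <- run_layers(frames, cfg)
  fan_tot <- sapply(res, function(x) sum(x$fan))
  w_half <- sq$theta / 2 / g$deg_per_pixel      # half-width in cells
  # aggregate by rounded half-width
  agg <- tapply(fan_tot, round(w_half), sum)
  best_w <- as.numeric(names(agg))[which.max(agg)]
  expect_lte(abs(best_w - cfg$delta_x), 1)
})

test_that("fan-in activity translates with the stimulus until clipping", {
  cfg <- network_config()
  g <- test_geom()
  mk <- function(off) {
    sq <- render_sequence(looming_spec(l = 0.3, v = 1000 * 0.3 / 20,
                                       start_theta = 16, angle_offset = off), g)
    frames <- lapply(seq_len(dim(sq$frames)[3]), function(k) sq$frames[, , k])
    res <- run_layers(frames, cfg)
    Reduce(`+`, lapply(res, function(x) x$fan))
  }
  f0 <- mk(0)
  # offset of 2 cells: 2 * px_w / (fov_h / 2)
  f2 <- mk(2 * test_geom()$px_w / (test_geom()$fov_h / 2))
  shifted <- lgmdsim:::shift_grid(f0, 0L, 2L)
  expect_gt(sum(f0), 0)
  # same total activity and same pattern up to the 2-cell translation
  expect_equal(sum(f2), sum(f0), tolerance = 0.15 * sum(f0))
  expect_gt(stats::cor(as.vector(f2), as.vector(shifted)), 0.85)
})

test_that("LGMD with zero input decays silently; sustained fan input fires periodically", {
  cfg <- network_config(w_inh = 0)
  zero <- matrix(0, 24, 32)
  st <- list(vm = 0.12)   # below the firing threshold
  vs <- numeric(10)
  for (k in 1:10) {
    out <- lgmd_step(zero, zero, zero, st, cfg)
    st <- out$state
    vs[k] <- out$vm
    expect_equal(out$n_spikes, 0)
  }
  expect_true(all(diff(vs) < 0) && all(vs > 0))   # decay towards rest

  # constant suprathreshold fan drive: inter-spike interval matches the
  # closed-form period oracle as the substep shrinks
  fan <- matrix(0, 24, 32); fan[12, 16] <- 10    # I_exc = w_exc * 10 = 2
  cfg_fine <- network_config(w_inh = 0, n_substeps = 100)
  st <- NULL; spikes <- numeric(0)
  for (k in 1:60) {
    out <- lgmd_step(fan, zero, zero, st, cfg_fine)
    st <- out$state
    if (out$n_spikes > 0) spikes <- c(spikes, (k - 1) * 10 + out$spike_offsets)
  }
  isi <- diff(spikes)
  t_theory <- iaf_period(cfg$lgmd, 2)
  expect_equal(mean(isi[-1]), t_theory, tolerance = 0.05 * t_theory)
})

test_that("angular threshold estimate is linear in the fan-in offsets", {
  g <- test_geom()
  c1 <- network_config(delta_x = 1, delta_y = 1)
  expect_equal(unname(angular_threshold_estimate(c1, g)["x"]),
               2 * g$deg_per_pixel)
  c5 <- network_config(delta_x = 5, delta_y = 6)
  est <- angular_threshold_estimate(c5, g)
  expect_equal(unname(est["x"]), 10 * g$deg_per_pixel)
  expect_equal(unname(est["y"]), 12 * g$deg_per_pixel)
  c10 <- network_config(delta_x = 10, delta_y = 12)
  expect_equal(angular_threshold_estimate(c10, g),
               2 * angular_threshold_estimate(c5, g))
})

test_that("full model: looming yields rise-peak-decay before collision, blank is silent", {
  cfg <- network_config()
  g <- test_geom()
  sim <- run_model(render_sequence(looming_spec(l = 0.3, v = 1000 * 0.3 / 40), g),
                   cfg)
  expect_gt(length(sim$spikes), 0)
  pk <- extract_peak(sim$rate)
  expect_true(pk$responded)
  expect_lt(pk$peak_time, 0)             # peaks before collision
  # rate decays after the peak: mean rate in the last quarter of the
  # post-peak window is below half the peak
  after <- sim$rate$hz[sim$rate$time_ms > pk$peak_time]
  tail_mean <- mean(after[seq(floor(3 * length(after) / 4), length(after))])
  expect_lt(tail_mean, 0.5 * pk$peak_rate)
  # rises before the peak
  before <- sim$rate$hz[sim$rate$time_ms < pk$peak_time]
  expect_lt(mean(before[1:floor(length(before) / 4)]), 0.5 * pk$peak_rate)

  # a blank sequence produces no spikes at all
  blank_spec <- looming_spec(l = 0.3, v = 10, contrast_ratio = 1)
  sim0 <- run_model(render_sequence(blank_spec, g), cfg)
  expect_length(sim0$spikes, 0)

  # rate integrates back to the spike count (within truncation error)
  expect_equal(sum(sim$rate$hz) / 1000, length(sim$spikes),
               tolerance = 0.01 * max(length(sim$spikes), 1))
})

test_that("receding stimuli evoke far fewer spikes than matched looms", {
  cfg <- network_config()
  g <- test_geom()
  loom <- run_model(render_sequence(looming_spec(l = 0.3, v = 10), g), cfg)
  rec <- run_model(render_sequence(looming_spec(mode = "receding", l = 0.3,
                                                v = 10, start_theta = 40), g),
                   cfg)
  expect_lt(length(rec$spikes), length(loom$spikes))
  # and the receding membrane potential is inhibition-dominated: its
  # deflection deepens monotonically with the inhibitory gain
  troughs <- sapply(c(0.001, 0.005, 0.01, 0.02), function(wi) {
    cfg_i <- network_config(w_inh = wi)
    min(run_model(render_sequence(looming_spec(mode = "receding", l = 0.3,
                                               v = 10, start_theta = 40), g),
                  cfg_i)$vm)
  })
  expect_true(all(diff(troughs) <= 1e-9))
  # positive response magnitude never increases with stronger inhibition
  rates <- sapply(c(0.001, 0.005, 0.01, 0.02), function(wi) {
    cfg_i <- network_config(w_inh = wi)
    max(run_model(render_sequence(looming_spec(mode = "receding", l = 0.3,
                                               v = 10, start_theta = 40), g),
                  cfg_i)$rate$hz)
  })
  expect_true(all(diff(rates) <= 1e-9))
})

test_that("simulations are deterministic and reject mismatched inputs", {
  cfg <- network_config()
  g <- test_geom()
  sq <- short_loom(lov = 20)
  s1 <- run_model(sq, cfg)
  s2 <- run_model(sq, cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$layers, s2$layers)
  expect_error(run_model(list(), cfg), "frame_sequence")
  expect_error(lamina_step(1:5, NULL, cfg), "matrix")
})
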