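# Shared fixtures for the test suite. Everything is generated in code at
# test time; simulations here are kept short so the whole suite stays fast.

test_geom <- function() camera_geometry()

# A short looming sequence (few frames), for smoke-level pipeline tests.
short_loom <- function(lov = 30, shape = "solid_square", start_theta = 10,
                       angle_offset = 0) {
  render_sequence(
    looming_spec(shape = shape, l = 0.3, v = 1000 * 0.3 / lov,
                 start_theta = start_theta, angle_offset = angle_offset),
    test_geom())
}

# Brute-force centre/surround convolution oracle (direct double loop with
# replicated borders), independent of the shift-and-add implementation.
brute_centre_surround <- function(frame, surround_weight) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- frame[r, c]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- min(max(r + dr, 1), h)
        cc <- min(max(c + dc, 1), w)
        acc <- acc + surround_weight * frame[rr, cc]
      }
      out[r, c] <- acc
    }
  }
  out
}

# 1-D edge sequence: a dark edge entering from the left and moving right at
# `step` cells per frame on an n-cell wide strip (3 rows so the kernel has a
# vertical surround). Returns a frame_sequence-like list of raw matrices.
moving_edge_frames <- function(n_frames, width = 20, step = 1, from = 3) {
  lapply(seq_len(n_frames), function(k) {
    edge <- from + (k - 1) * step
    fr <- matrix(255, 5, width)
    if (edge >= 1) fr[, seq_len(min(edge, width))] <- 0
    fr
  })
}

# Run the network layers manually over raw frames (list of matrices),
# returning the final layer outputs for every frame.
run_layers <- function(frames, config) {
  st <- list(photo = NULL, lamina = NULL, medulla = NULL, dir = NULL,
             fan = NULL)
  lam_buf <- vector("list", length(frames))
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    ph <- neuron_step(st$photo, config$photo, frames[[k]] / 255)
    st$photo <- list(vm = ph$vm)
    lam <- lamina_step(ph$output, st$lamina, config)
    st$lamina <- lam$state
    lam_buf[[k]] <- lam$output
    delayed <- if (k > config$onoff_delay) lam_buf[[k - config$onoff_delay]]
               else NULL
    med <- medulla_onoff_step(lam$output, delayed, st$medulla, config)
    st$medulla <- med$state
    dir <- directional_step(med$on, med$off, st$dir, config)
    st$dir <- dir$state
    fan <- chiasma_fanin_step(dir$dir, st$fan, config)
    st$fan <- fan$state
    out[[k]] <- list(lamina = lam$output, on = med$on, off = med$off,
                     dir = dir$dir, fan = fan$output)
  }
  out
}
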