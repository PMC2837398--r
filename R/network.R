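# The emergent-nonlinearity network: photoreceptors -> lamina centre/surround
# -> medulla on/off transient detectors -> four directionally selective
# ensembles -> chiasma fan-in -> LGMD integrate-and-fire output.
#
# The angular threshold of the LGMD is not computed anywhere in the network;
# it emerges from the fan-in geometry: each unit of the pre-synaptic fan
# collects outward-moving-edge activity at offsets (+/- delta_x, +/- delta_y)
# around its retinotopic position, so units under the centre of an expanding
# object are maximally driven exactly when the object's edges sit at those
# offsets, i.e. when the object subtends about 2 * delta_x cells of visual
# angle. Feed-forward inhibition from the summed on/off activity terminates
# the response once the object grows past that size.

#' Network configuration
#'
#' All neuron parameters, layer gains and the fan-in geometry of the LGMD
#' network. The defaults are the shipped calibration for the nominal
#' 25-degree angular-threshold condition (`delta_x = delta_y = 5` cells at
#' 2.33 deg/cell gives the nearest representable threshold, 23.3 deg); see
#' [angular_threshold_estimate()].
#'
#' @param photo,lamina,medulla,directional,chiasma,lgmd [neuron_params()] per
#'   layer. All layers but the LGMD are linear-threshold; the LGMD is
#'   integrate-and-fire.
#' @param surround_weight weight of each of the 8 surround cells in the
#'   lamina centre/surround kernel (centre weight is +1; the default -1/8
#'   makes the kernel zero-sum so uniform fields are rejected).
#' @param onoff_delay delay, in frames, between the direct and the delayed
#'   pathway of the medulla transient detectors.
#' @param delta_x,delta_y fan-in half-offsets in photoreceptor cells: the
#'   distances at which each fan unit samples outward-selective motion
#'   activity. These set the angular threshold.
#' @param coincidence_threshold synaptic threshold subtracted from the
#'   combined on/off pair in the directional ensembles (suppresses
#'   noise-driven coincidences).
#' @param coincidence_rule how the on/off pair is combined: `"min"`
#'   (default; the elementwise minimum is a graded AND, active only when
#'   both partners are active regardless of their absolute scale), `"sum"`
#'   (thresholded sum) or `"product"`. The sum variant lets a single strong
#'   partner cross threshold on its own, which dilutes the directional
#'   selectivity for fast edges.
#' @param trail_extent extent, in cells, of the trailing receptive field of
#'   the offset partner in each directional ensemble. An edge moving at more
#'   than one cell per frame leaves its offset trace several cells behind
#'   the onset trace; the ensemble takes the strongest offset within this
#'   window. 1 restricts the pairing to the immediate neighbour.
#' @param lateral_weight weight of each of the 8 neighbours in the lateral
#'   excitation that spreads and smooths activity across the pre-synaptic fan.
#' @param fan_sample_extent half-width, in cells, of the window over which a
#'   fan unit samples each directional ensemble around its nominal offset
#'   (`delta +/- fan_sample_extent`, strongest activity wins). The retinal
#'   grid is even-sized, so an object centred on the optical axis projects
#'   half a cell off the unit lattice; a 1-cell tolerance absorbs that and
#'   sets the resolution of the angular threshold (about +/- 2 cells of
#'   visual angle).
#' @param fanin_rule how a fan unit combines the four sampled ensembles:
#'   `"opposite_pairs"` (default) responds to the coincidence of opposing
#'   outward ensembles — boundaries expanding symmetrically about the unit at
#'   `+delta` and `-delta` together — which is what ties the response to a
#'   specific object size; `"count"` is a simple thresholded sum gated by the
#'   number of active ensembles (`chiasma_threshold`).
#' @param fan_leak weight with which each sampled ensemble also drives the
#'   fan unit on its own, without a coincident partner (opposite_pairs rule
#'   only). The unit is maximally excited by paired expanding boundaries but
#'   not absolutely silent otherwise; this weak background grows with the
#'   total expanding-edge activity during an approach and gives the LGMD its
#'   gradual rising phase before the angular-threshold burst.
#' @param chiasma_threshold for `fanin_rule = "count"`: minimum number (of 4)
#'   of directional ensembles that must be simultaneously active at the
#'   sampled offsets for a fan unit to respond.
#' @param w_exc gain of the excitatory fan input to the LGMD (0.2 in all
#'   reference experiments).
#' @param w_inh gain of the feed-forward inhibition (summed medulla on/off
#'   activity) onto the LGMD.
#' @param noise_sigma sensor noise s.d. in luminance units, used by the
#'   experiment protocols to make repetitions differ.
#' @param seed default RNG seed for the above.
#' @param n_substeps integrate-and-fire sub-steps per video frame for the
#'   LGMD (> 1 raises the discrete-time firing-rate ceiling above one spike
#'   per frame).
#' @return an object of class `network_config` (schema version 1).
#' @examples
#' cfg <- network_config()
#' angular_threshold_estimate(cfg, camera_geometry())
#' @export
network_config <- function(photo = neuron_params(R = 1, Cm = 20, v_thresh = 0,
                                                 dt = 10, mode = "LT"),
                           lamina = neuron_params(R = 1, Cm = 20, v_thresh = 0.01,
                                                  dt = 10, mode = "LT"),
                           medulla = neuron_params(R = 2, Cm = 5, v_thresh = 0.01,
                                                   dt = 10, mode = "LT"),
                           directional = neuron_params(R = 1, Cm = 10, v_thresh = 0,
                                                       dt = 10, mode = "LT"),
                           chiasma = neuron_params(R = 1, Cm = 10, v_thresh = 0.01,
                                                   dt = 10, mode = "LT"),
                           lgmd = neuron_params(R = 1, Cm = 15, v_thresh = 0.15,
                                                dt = 10, mode = "IAF"),
                           surround_weight = -1 / 8,
                           onoff_delay = 1L,
                           delta_x = 5L, delta_y = 5L,
                           coincidence_threshold = 0.02,
                           coincidence_rule = c("min", "sum", "product"),
                           trail_extent = 3L,
                           lateral_weight = 0.2,
                           fan_sample_extent = 1L,
                           fanin_rule = c("opposite_pairs", "count"),
                           fan_leak = 0,
                           chiasma_threshold = 2L,
                           w_exc = 0.2, w_inh = 0.05,
                           noise_sigma = 2, seed = 1L,
                           n_substeps = 4L) {
  coincidence_rule <- match.arg(coincidence_rule)
  fanin_rule <- match.arg(fanin_rule)
  for (p in list(photo, lamina, medulla, directional, chiasma, lgmd))
    if (!inherits(p, "neuron_params"))
      stop("layer parameters must be neuron_params objects", call. = FALSE)
  stopifnot(delta_x >= 1, delta_y >= 1, w_exc >= 0, w_inh >= 0,
            onoff_delay >= 1, chiasma_threshold >= 1, chiasma_threshold <= 4,
            coincidence_threshold >= 0, lateral_weight >= 0, fan_leak >= 0,
            trail_extent >= 1, noise_sigma >= 0, n_substeps >= 1)
  structure(
    list(schema_version = 1L,
         photo = photo, lamina = lamina, medulla = medulla,
         directional = directional, chiasma = chiasma, lgmd = lgmd,
         surround_weight = surround_weight,
         onoff_delay = as.integer(onoff_delay),
         delta_x = as.integer(delta_x), delta_y = as.integer(delta_y),
         coincidence_threshold = coincidence_threshold,
         coincidence_rule = coincidence_rule,
         trail_extent = as.integer(trail_extent),
         lateral_weight = lateral_weight,
         fan_sample_extent = as.integer(fan_sample_extent),
         fanin_rule = fanin_rule, fan_leak = fan_leak,
         chiasma_threshold = as.integer(chiasma_threshold),
         w_exc = w_exc, w_inh = w_inh,
         noise_sigma = noise_sigma, seed = as.integer(seed),
         n_substeps = as.integer(n_substeps)),
    class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(paste0("<network_config> delta=(%d,%d) cells, w_exc=%g w_inh=%g, ",
                     "coincidence=%s>=%g, chiasma>=%d/4\n"),
              x$delta_x, x$delta_y, x$w_exc, x$w_inh,
              x$coincidence_rule, x$coincidence_threshold, x$chiasma_threshold))
  invisible(x)
}

#' Angular threshold implied by the fan-in geometry
#'
#' The preferred full angular size of the network: an expanding object
#' maximally excites the fan when its edges sit at `+/- delta` cells around
#' the object centre, i.e. at a full size of `2 * delta * deg_per_pixel`
#' degrees. This is a pure function of the fan-in offsets and the optics;
#' nothing in the simulation computes it. The resolution bound on the
#' realised threshold is about +/- 2 cells of visual angle.
#'
#' @param config a [network_config()].
#' @param geom a [camera_geometry()].
#' @return named vector with components `x` and `y`, degrees.
#' @export
angular_threshold_estimate <- function(config, geom = camera_geometry()) {
  if (!inherits(config, "network_config")) stop("'config' must be a network_config",
                                                call. = FALSE)
  c(x = 2 * config$delta_x * geom$deg_per_pixel,
    y = 2 * config$delta_y * geom$deg_per_pixel)
}

# ---------------------------------------------------------------------------
# Layer steps. Each takes explicit state (list of vm matrices) and returns
# list(state, output...). They are exposed so that single stages can be
# probed against brute-force oracles.

#' Lamina centre/surround step
#'
#' Drives the lamina LT layer with the centre-minus-surround filtered
#' photoreceptor output. The kernel (centre +1, eight surround cells at
#' `surround_weight`, default -1/8) is zero-sum, so uniform illumination maps
#' to zero activity and luminance edges are enhanced.
#'
#' @param frame photoreceptor activity grid (luminance normalised to [0, 1]).
#' @param state lamina state (list with `vm`) or `NULL` to start at rest.
#' @param config a [network_config()].
#' @return list with `state` (updated) and `output` (activity grid).
#' @export
lamina_step <- function(frame, state, config) {
  if (!is.matrix(frame)) stop("'frame' must be a matrix", call. = FALSE)
  kern <- matrix(config$surround_weight, 3, 3)
  kern[2, 2] <- 1
  # replicate padding: a uniform field is rejected exactly, with no
  # spurious response at the border of the visual field
  drive <- conv3x3(frame, kern, pad = "replicate")
  st <- neuron_step(state, config$lamina, drive)
  list(state = list(vm = st$vm), output = st$output)
}

#' Medulla on/off transient-detector step
#'
#' Onset cells respond to luminance-driven increases of lamina activity
#' (excitation minus a delayed copy), offset cells to decreases (delayed copy
#' minus current). Sustained static input therefore yields zero after
#' `onoff_delay` frames; during warm-up (insufficient history) the output is
#' zero by definition.
#'
#' @param lamina_out current lamina activity grid.
#' @param delayed lamina activity `onoff_delay` frames ago, or `NULL` during
#'   warm-up.
#' @param state list with `on` and `off` neuron states, or `NULL`.
#' @param config a [network_config()].
#' @return list with `state`, `on` and `off` activity grids.
#' @export
medulla_onoff_step <- function(lamina_out, delayed, state, config) {
  zero <- lamina_out * 0
  if (is.null(delayed)) {
    st_on <- neuron_step(state$on, config$medulla, zero)
    st_off <- neuron_step(state$off, config$medulla, zero)
    return(list(state = list(on = list(vm = st_on$vm), off = list(vm = st_off$vm)),
                on = zero, off = zero))
  }
  st_on <- neuron_step(state$on, config$medulla, rect(lamina_out - delayed))
  st_off <- neuron_step(state$off, config$medulla, rect(delayed - lamina_out))
  list(state = list(on = list(vm = st_on$vm), off = list(vm = st_off$vm)),
       on = st_on$output, off = st_off$output)
}

#' Directionally selective ensemble step
#'
#' For each of the four cardinal directions, an ensemble cell combines the
#' onset cell at its own position with the offset cell at the trailing
#' neighbour (the location an edge moving in that direction has just
#' vacated). The cell must see both partners active together: the default
#' `"min"` rule takes the elementwise minimum of the pair (a graded AND),
#' `"product"` multiplies them, and `"sum"` adds them before the coincidence
#' threshold is subtracted.
#'
#' @param on,off medulla activity grids.
#' @param state list of four neuron states (`right`, `left`, `down`, `up`) or
#'   `NULL`.
#' @param config a [network_config()].
#' @return list with `state` and `dir`, a list of four activity grids named
#'   `right` (+x), `left` (-x), `down` (+y, increasing row) and `up` (-y).
#' @export
directional_step <- function(on, off, state, config) {
  pair <- function(off_shifted) {
    switch(config$coincidence_rule,
           min = rect(pmin(on, off_shifted) - config$coincidence_threshold),
           sum = rect(on + off_shifted - config$coincidence_threshold),
           product = rect(on * off_shifted - config$coincidence_threshold))
  }
  # strongest offset within the trailing window (edges faster than one cell
  # per frame leave their offset trace further behind)
  trail <- function(dr, dc) {
    out <- shift_grid(off, dr, dc)
    for (k in seq_len(config$trail_extent - 1L))
      out <- pmax(out, shift_grid(off, dr * (k + 1L), dc * (k + 1L)))
    out
  }
  drives <- list(right = pair(trail(0L, 1L)),
                 left  = pair(trail(0L, -1L)),
                 down  = pair(trail(1L, 0L)),
                 up    = pair(trail(-1L, 0L)))
  out <- list(); newstate <- list()
  for (d in names(drives)) {
    st <- neuron_step(state[[d]], config$directional, drives[[d]])
    newstate[[d]] <- list(vm = st$vm)
    out[[d]] <- st$output
  }
  list(state = newstate, dir = out)
}

#' Chiasma fan-in step
#'
#' Each unit of the LGMD pre-synaptic fan samples the outward-selective
#' directional ensembles at offsets around its retinotopic position:
#' rightward motion at `+delta_x`, leftward at `-delta_x`, downward at
#' `+delta_y` and upward at `-delta_y`. Under the default
#' `"opposite_pairs"` rule a unit is driven by the coincidence (elementwise
#' minimum) of each opposing pair — leftward-at-`-delta_x` with
#' rightward-at-`+delta_x`, and upward with downward — so it responds only
#' when boundaries are moving apart symmetrically about it, which happens
#' precisely when an expanding object centred on the unit spans
#' `2 * delta` cells. Under the `"count"` rule the four samples are summed
#' wherever at least `chiasma_threshold` of them are active. Lateral
#' excitation then spreads the activity to the 8 neighbours before the LT
#' threshold is applied.
#'
#' @param dir list of four directional grids as produced by
#'   [directional_step()].
#' @param state fan neuron state or `NULL`.
#' @param config a [network_config()].
#' @return list with `state` and `output` (fan activity grid).
#' @export
chiasma_fanin_step <- function(dir, state, config) {
  # dilate each map along its motion axis by the sampling tolerance
  ext <- config$fan_sample_extent
  dilate <- function(m, dr, dc) {
    out <- m
    for (k in seq_len(ext)) out <- pmax(out, shift_grid(m, dr * k, dc * k),
                                        shift_grid(m, -dr * k, -dc * k))
    out
  }
  d_right <- dilate(dir$right, 0L, 1L)
  d_left  <- dilate(dir$left, 0L, 1L)
  d_down  <- dilate(dir$down, 1L, 0L)
  d_up    <- dilate(dir$up, 1L, 0L)
  s_right <- shift_grid(d_right, 0L, -config$delta_x)  # value at c+delta_x
  s_left  <- shift_grid(d_left,  0L,  config$delta_x)  # value at c-delta_x
  s_down  <- shift_grid(d_down, -config$delta_y, 0L)   # value at r+delta_y
  s_up    <- shift_grid(d_up,    config$delta_y, 0L)   # value at r-delta_y
  raw <- if (config$fanin_rule == "opposite_pairs") {
    pmin(s_right, s_left) + pmin(s_down, s_up) +
      config$fan_leak * (s_right + s_left + s_down + s_up)
  } else {
    hits <- (s_right > 0) + (s_left > 0) + (s_down > 0) + (s_up > 0)
    (s_right + s_left + s_down + s_up) * (hits >= config$chiasma_threshold)
  }
  smoothed <- raw + config$lateral_weight * neighbour_sum(raw)
  st <- neuron_step(state, config$chiasma, smoothed)
  list(state = list(vm = st$vm), output = st$output)
}

#' LGMD integrate-and-fire step
#'
#' The LGMD integrates the summed fan excitation (gain `w_exc`) against the
#' feed-forward inhibition formed by the summed medulla on/off activity
#' (gain `w_inh`) and produces spikes. The inputs are image-driven activity
#' grids only; no stage of the pipeline represents angular size or angular
#' velocity explicitly. With `n_substeps > 1` the membrane equation is
#' sub-stepped within the frame (the input current is held constant), which
#' raises the firing-rate ceiling above one spike per frame.
#'
#' @param fan fan activity grid from [chiasma_fanin_step()].
#' @param on,off medulla activity grids (the inhibitory pathway).
#' @param state LGMD state (list with `vm`) or `NULL`.
#' @param config a [network_config()].
#' @return list with `state`, `vm` (potential at end of frame), `n_spikes`
#'   (spikes emitted this frame), `spike_offsets` (times of those spikes
#'   within the frame, ms from frame start), `i_exc` and `i_inh`.
#' @export
lgmd_step <- function(fan, on, off, state, config) {
  i_exc <- config$w_exc * sum(fan)
  i_inh <- config$w_inh * (sum(on) + sum(off))
  input <- i_exc - i_inh
  p <- config$lgmd
  nsub <- config$n_substeps
  dts <- p$dt / nsub
  vm <- if (is.null(state)) 0 else state$vm
  offsets <- numeric(0)
  for (s in seq_len(nsub)) {
    vm <- vm + dts * (-vm / p$tau + input / p$Cm)
    if (vm >= p$v_thresh) {
      offsets <- c(offsets, (s - 1) * dts)
      vm <- 0
    }
  }
  list(state = list(vm = vm), vm = vm, n_spikes = length(offsets),
       spike_offsets = offsets, i_exc = i_exc, i_inh = i_inh)
}

#' Run the full network on a stimulus sequence
#'
#' Runs every layer frame by frame and collects per-layer mean population
#' activity, the LGMD membrane potential, spike times and a smoothed firing
#' rate. Fully deterministic for a given input sequence.
#'
#' @param seq a [render_sequence()] result (optionally with sensor noise).
#' @param config a [network_config()].
#' @param rate_sigma Gaussian smoothing sigma for the firing-rate estimate,
#'   ms.
#' @param store_grids if `TRUE`, keep the per-frame fan activity maps
#'   (memory-heavy; off by default).
#' @return an object of class `lgmd_sim`: list with `times` (frame
#'   timestamps, ms), `layers` (data frame of per-layer mean activity and
#'   LGMD input currents per frame), `vm` (LGMD membrane potential per
#'   frame), `spikes` (spike times, ms), `rate` (data frame `time_ms`, `hz`
#'   on a 1 ms grid), `theta` (stimulus angular size per frame), `spec`,
#'   `config`, and optionally `fan_maps`.
#' @examples
#' \donttest{
#' sim <- run_model(render_sequence(looming_spec(l = 0.2, v = 10)),
#'                  network_config())
#' }
#' @export
run_model <- function(seq, config = network_config(), rate_sigma = 20,
                      store_grids = FALSE) {
  if (!inherits(seq, "frame_sequence")) stop("'seq' must be a frame_sequence",
                                             call. = FALSE)
  if (!inherits(config, "network_config")) stop("'config' must be a network_config",
                                                call. = FALSE)
  n <- dim(seq$frames)[3]
  d <- config$onoff_delay
  lam_buf <- vector("list", n)
  st <- list(photo = NULL, lamina = NULL, medulla = NULL, dir = NULL,
             fan = NULL, lgmd = NULL)
  layers <- data.frame(time_ms = seq$times, photo = 0, lamina = 0,
                       medulla_on = 0, medulla_off = 0, directional = 0,
                       fan = 0, i_exc = 0, i_inh = 0)
  vm <- numeric(n)
  spikes <- numeric(0)
  fan_maps <- if (store_grids) vector("list", n) else NULL

  for (k in seq_len(n)) {
    ph <- neuron_step(st$photo, config$photo, seq$frames[, , k] / 255)
    st$photo <- list(vm = ph$vm)
    lam <- lamina_step(ph$output, st$lamina, config)
    st$lamina <- lam$state
    lam_buf[[k]] <- lam$output
    delayed <- if (k > d) lam_buf[[k - d]] else NULL
    med <- medulla_onoff_step(lam$output, delayed, st$medulla, config)
    st$medulla <- med$state
    dir <- directional_step(med$on, med$off, st$dir, config)
    st$dir <- dir$state
    fan <- chiasma_fanin_step(dir$dir, st$fan, config)
    st$fan <- fan$state
    out <- lgmd_step(fan$output, med$on, med$off, st$lgmd, config)
    st$lgmd <- out$state
    vm[k] <- out$vm
    if (out$n_spikes > 0) spikes <- c(spikes, seq$times[k] + out$spike_offsets)
    layers$photo[k] <- mean(ph$output)
    layers$lamina[k] <- mean(lam$output)
    layers$medulla_on[k] <- mean(med$on)
    layers$medulla_off[k] <- mean(med$off)
    layers$directional[k] <- mean(dir$dir$right + dir$dir$left +
                                  dir$dir$down + dir$dir$up) / 4
    layers$fan[k] <- mean(fan$output)
    layers$i_exc[k] <- out$i_exc
    layers$i_inh[k] <- out$i_inh
    if (store_grids) fan_maps[[k]] <- fan$output
  }

  t_grid <- seq(seq$times[1] - 3 * rate_sigma,
                seq$times[n] + seq$dt + 3 * rate_sigma, by = 1)
  rate <- data.frame(time_ms = t_grid,
                     hz = smooth_rate(spikes, t_grid, sigma = rate_sigma))
  structure(
    list(times = seq$times, layers = layers, vm = vm, spikes = spikes,
         rate = rate, theta = seq$theta, spec = seq$spec, config = config,
         fan_maps = fan_maps),
    class = "lgmd_sim")
}

#' @export
print.lgmd_sim <- function(x, ...) {
  cat(sprintf("<lgmd_sim> %d frames, %d spikes, peak rate %.1f Hz\n",
              length(x$times), length(x$spikes), max(x$rate$hz)))
  invisible(x)
}
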