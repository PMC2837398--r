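# Synthetic visual stimulation: looming, receding and uniformly expanding
# objects rendered onto the simulated photoreceptor raster.
#
# The raster emulates a uniformly distributed compound eye of 32 x 24
# photoreceptors covering a 74.65 x 56.25 degree field of view, i.e. an
# angular resolution of about 2.33 degrees per cell. An object of half-length
# l approaching at constant speed v subtends the full angle
#   theta(t) = 2 * atan(l / (|v| * t)),   t = time remaining to collision,
# so the whole angular time course is determined by the ratio l/|v| (ms)
# alone. Luminance is on a 0..255 scale, dark object on bright background.

#' Camera/compound-eye geometry
#'
#' @param fov_h,fov_v horizontal and vertical field of view, degrees.
#' @param grid_w,grid_h photoreceptor columns and rows.
#' @param deg_per_pixel nominal angular resolution, degrees per cell. Checked
#'   for consistency with `fov_h/grid_w` and `fov_v/grid_h` (within rounding).
#' @return an object of class `camera_geometry`.
#' @examples
#' camera_geometry()
#' @export
camera_geometry <- function(fov_h = 74.65, fov_v = 56.25,
                            grid_w = 32L, grid_h = 24L,
                            deg_per_pixel = 2.33) {
  stopifnot(fov_h > 0, fov_v > 0, grid_w >= 2, grid_h >= 2, deg_per_pixel > 0)
  px_w <- fov_h / grid_w
  px_h <- fov_v / grid_h
  if (abs(px_w - deg_per_pixel) > 0.05 * deg_per_pixel ||
      abs(px_h - deg_per_pixel) > 0.05 * deg_per_pixel)
    stop("'deg_per_pixel' is inconsistent with fov/grid (beyond rounding)",
         call. = FALSE)
  structure(
    list(fov_h = fov_h, fov_v = fov_v, grid_w = as.integer(grid_w),
         grid_h = as.integer(grid_h), deg_per_pixel = deg_per_pixel,
         px_w = px_w, px_h = px_h),
    class = "camera_geometry")
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat(sprintf("<camera_geometry> %dx%d cells, %.2f x %.2f deg (%.3f deg/cell)\n",
              x$grid_w, x$grid_h, x$fov_h, x$fov_v, x$deg_per_pixel))
  invisible(x)
}

#' Angular size of an approaching object
#'
#' Full subtended angle `theta(t) = 2 * atan(l / (|v| * t))` of an object of
#' half-length `l` approaching at speed `v`, evaluated `t` milliseconds
#' before collision. Monotonically increasing as `t` decreases; at
#' `t = 1000 * l/|v|` (distance equal to the half-length) the object subtends
#' exactly 90 degrees.
#'
#' @param l half-length of the object, metres (> 0).
#' @param v approach speed, m/s (its absolute value is used).
#' @param t time remaining to collision, ms (> 0; vectorised).
#' @return full angular size in degrees.
#' @examples
#' angular_size(0.3, 10, 30)  # l/|v| = 30 ms at t = 30 ms: 90 degrees
#' @export
angular_size <- function(l, v, t) {
  stop_if_not_scalar(l, "l"); stop_if_not_scalar(v, "v")
  if (l <= 0 || v == 0) stop("'l' and '|v|' must be positive", call. = FALSE)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be positive (time remaining to collision)", call. = FALSE)
  2 * atan(1000 * l / (abs(v) * t)) * 180 / pi
}

#' Looming stimulus specification
#'
#' Describes one synthetic stimulation trial. Time is measured in ms with the
#' projected collision at t = 0 (so looming trials run at negative times).
#'
#' In `"looming"` mode the angular size follows the approach law above between
#' `t_start` and `t_end` (< 0). In `"receding"` mode the object starts at
#' angular size `start_theta` and shrinks as it moves away at speed `|v|`
#' starting at `t_start`. In `"uniform_expansion"` mode the angular size grows
#' linearly at `expansion_rate` degrees/ms from `start_theta`.
#'
#' A short static hold (`hold_ms`) of the first frame is prepended so that
#' onset transients caused by the appearance of the object die out before the
#' motion begins.
#'
#' @param shape one of `"solid_square"`, `"solid_circle"`,
#'   `"checkerboard_square"`, `"concentric_squares"`.
#' @param l half-length of the object, metres.
#' @param v speed, m/s (sign is ignored; the `mode` selects the direction).
#' @param contrast_ratio luminance contrast ratio `L_high / L_low` (>= 1;
#'   1 means no contrast, `Inf` the ideal dark-on-bright stimulus).
#' @param angle_offset azimuthal displacement of the stimulus centre as a
#'   fraction of the half field of view (0 = centred, 1 = centre at the edge
#'   of the field).
#' @param mode `"looming"`, `"receding"` or `"uniform_expansion"`.
#' @param t_start,t_end simulated time window, ms. For looming, `t_end` must
#'   be negative (the simulation stops before collision) and `t_start`
#'   defaults to the time at which the object subtends `start_theta` degrees.
#'   For the other modes the window defaults to `[0, duration]` of 1000 ms.
#' @param start_theta initial angular size in degrees (looming: size at
#'   `t_start` when `t_start` is not given; receding/uniform expansion:
#'   size at motion onset).
#' @param expansion_rate uniform-expansion rate, degrees/ms.
#' @param frame_rate frames per second (default 100).
#' @param hold_ms static hold of the first frame before motion onset, ms.
#' @param n_checks,n_rings texture granularity for the checkerboard (checks
#'   per side) and concentric-squares (alternating bands from the centre)
#'   patterns. The defaults are fine relative to the photoreceptor raster,
#'   as in the physical experiments where the screen texture was much finer
#'   than an ommatidial acceptance angle: the pattern is area-averaged to a
#'   mid-grey by the optics for most of the approach and only becomes
#'   resolvable very late.
#' @return an object of class `looming_spec` with derived field `l_over_v`
#'   (ms).
#' @examples
#' looming_spec(l = 0.3, v = 10)          # l/|v| = 30 ms approach
#' looming_spec(mode = "receding", v = 10)
#' @export
looming_spec <- function(shape = c("solid_square", "solid_circle",
                                   "checkerboard_square", "concentric_squares"),
                         l = 0.3, v = 10, contrast_ratio = Inf,
                         angle_offset = 0,
                         mode = c("looming", "receding", "uniform_expansion"),
                         t_start = NULL, t_end = NULL,
                         start_theta = 2, expansion_rate = 0.05,
                         frame_rate = 100, hold_ms = 100,
                         n_checks = 16L, n_rings = 3L) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  stopifnot(l > 0, abs(v) > 0, contrast_ratio >= 1,
            angle_offset >= 0, angle_offset <= 1,
            start_theta > 0, start_theta < 180,
            expansion_rate > 0, frame_rate > 0, hold_ms >= 0)
  lov <- 1000 * l / abs(v)
  if (mode == "looming") {
    # time at which theta == start_theta: t = l/|v| / tan(theta/2)
    if (is.null(t_start))
      t_start <- -lov / tan(start_theta / 2 * pi / 180)
    if (is.null(t_end)) t_end <- -1000 / frame_rate
    if (t_end >= 0) stop("looming stimuli must end before collision (t_end < 0)",
                         call. = FALSE)
    if (t_start >= t_end) stop("empty time window", call. = FALSE)
  } else {
    if (is.null(t_start)) t_start <- 0
    if (is.null(t_end)) t_end <- t_start + 1000
    if (t_start >= t_end) stop("empty time window", call. = FALSE)
  }
  structure(
    list(shape = shape, l = l, v = abs(v), l_over_v = lov,
         contrast_ratio = contrast_ratio, angle_offset = angle_offset,
         mode = mode, t_start = t_start, t_end = t_end,
         start_theta = start_theta, expansion_rate = expansion_rate,
         frame_rate = frame_rate, hold_ms = hold_ms,
         n_checks = as.integer(n_checks), n_rings = as.integer(n_rings)),
    class = "looming_spec")
}

#' @export
print.looming_spec <- function(x, ...) {
  cat(sprintf("<looming_spec> %s %s, l=%g m, v=%g m/s (l/|v|=%g ms), offset=%g\n",
              x$mode, x$shape, x$l, x$v, x$l_over_v, x$angle_offset))
  invisible(x)
}

# Angular size (deg) of the stimulus at simulated time t (ms), per mode.
# Times before motion onset (the hold period) clamp to the starting size.
stimulus_theta <- function(spec, t) {
  th <- switch(spec$mode,
    looming = {
      tt <- pmax(pmin(t, spec$t_end), spec$t_start)
      angular_size(spec$l, spec$v, -tt)
    },
    receding = {
      # object starts at distance d0 (where it subtends start_theta) and
      # moves away at |v|; same size law as looming with time reversed.
      d0 <- spec$l / tan(spec$start_theta / 2 * pi / 180)     # metres
      tt <- pmax(t, spec$t_start)
      d <- d0 + spec$v * (tt - spec$t_start) / 1000
      2 * atan(spec$l / d) * 180 / pi
    },
    uniform_expansion = {
      tt <- pmax(t, spec$t_start)
      spec$start_theta + spec$expansion_rate * (tt - spec$t_start)
    })
  pmin(th, 179.9)
}

#' Render one stimulus frame
#'
#' Rasterises the stimulus shape at its angular size at time `t` onto the
#' photoreceptor grid. Rendering happens in angular coordinates (azimuth,
#' elevation measured from the optical axis); cells partially covered by the
#' shape receive area-weighted luminance (the anti-aliasing a physical camera
#' performs), and anything outside the field of view is clipped. The
#' background is at luminance 255 and the object at `255 / contrast_ratio`.
#'
#' @param spec a [looming_spec()].
#' @param geom a [camera_geometry()].
#' @param t simulated time, ms.
#' @return a `grid_h` x `grid_w` luminance matrix in `[0, 255]`.
#' @examples
#' g <- camera_geometry()
#' fr <- render_frame(looming_spec(l = 0.3, v = 10), g, t = -100)
#' @export
render_frame <- function(spec, geom, t) {
  if (!inherits(spec, "looming_spec")) stop("'spec' must be a looming_spec",
                                            call. = FALSE)
  if (!inherits(geom, "camera_geometry")) stop("'geom' must be a camera_geometry",
                                               call. = FALSE)
  theta <- stimulus_theta(spec, t)
  a <- theta / 2                                   # half-size, degrees
  l_high <- 255
  l_low <- 255 / spec$contrast_ratio
  az0 <- spec$angle_offset * geom$fov_h / 2
  el0 <- 0
  h <- geom$grid_h; w <- geom$grid_w
  az <- (seq_len(w) - (w + 1) / 2) * geom$px_w     # column centres, deg
  el <- (seq_len(h) - (h + 1) / 2) * geom$px_h     # row centres, deg

  if (spec$shape == "solid_square") {
    # exact separable area coverage of an axis-aligned square
    covx <- pmax(0, (pmin(az + geom$px_w / 2, az0 + a) -
                     pmax(az - geom$px_w / 2, az0 - a))) / geom$px_w
    covy <- pmax(0, (pmin(el + geom$px_h / 2, el0 + a) -
                     pmax(el - geom$px_h / 2, el0 - a))) / geom$px_h
    cov <- outer(covy, covx)
  } else {
    cov <- supersampled_coverage(spec, geom, a, az0, el0)
  }
  l_high - (l_high - l_low) * cov
}

# Anti-aliased coverage of circular / textured shapes by ss x ss
# supersampling: evaluate an inside/dark predicate on sub-cell points, then
# average them back onto the cell grid.
supersampled_coverage <- function(spec, geom, a, az0, el0, ss = 4L) {
  h <- geom$grid_h; w <- geom$grid_w
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  # sub-sample angular coordinates; index = (cell - 1) * ss + sub
  azs <- as.vector(t(outer((seq_len(w) - (w + 1) / 2) * geom$px_w,
                           off * geom$px_w, `+`)))
  els <- as.vector(t(outer((seq_len(h) - (h + 1) / 2) * geom$px_h,
                           off * geom$px_h, `+`)))
  u <- matrix(azs - az0, nrow = h * ss, ncol = w * ss, byrow = TRUE)
  vv <- matrix(els - el0, nrow = h * ss, ncol = w * ss)
  dark <- switch(spec$shape,
    solid_circle = (u / a)^2 + (vv / a)^2 <= 1,
    checkerboard_square = {
      inside <- abs(u) <= a & abs(vv) <= a
      n <- spec$n_checks
      ix <- floor(pmin(pmax((u + a) / (2 * a), 0), 1 - 1e-9) * n)
      iy <- floor(pmin(pmax((vv + a) / (2 * a), 0), 1 - 1e-9) * n)
      inside & ((ix + iy) %% 2 == 0)
    },
    concentric_squares = {
      r <- pmax(abs(u), abs(vv)) / a
      band <- floor(pmin(r, 1 - 1e-9) * spec$n_rings)
      (r <= 1) & (band %% 2 == 0)
    },
    stop("unknown shape: ", spec$shape, call. = FALSE))
  dark <- matrix(as.numeric(dark), nrow = h * ss)
  agg <- rowsum(dark, group = rep(seq_len(h), each = ss))
  agg <- t(rowsum(t(agg), group = rep(seq_len(w), each = ss)))
  agg / (ss * ss)
}

#' Render a full stimulus sequence
#'
#' Renders frames at the spec's frame rate over `[t_start, t_end]`, with
#' `hold_ms` of static copies of the first frame prepended (timestamps before
#' `t_start`). For looming the angular size is strictly increasing across the
#' motion frames, for receding strictly decreasing, and for uniform expansion
#' it grows exactly linearly.
#'
#' @param spec a [looming_spec()].
#' @param geom a [camera_geometry()].
#' @return an object of class `frame_sequence`: list with `frames` (array
#'   `grid_h x grid_w x n`), `times` (ms, collision at 0 for looming),
#'   `theta` (angular size per frame, deg), `dt` (ms), `geom` and `spec`.
#' @examples
#' seq <- render_sequence(looming_spec(l = 0.3, v = 10), camera_geometry())
#' @export
render_sequence <- function(spec, geom = camera_geometry()) {
  if (!inherits(spec, "looming_spec")) stop("'spec' must be a looming_spec",
                                            call. = FALSE)
  dt <- 1000 / spec$frame_rate
  times <- seq(spec$t_start, spec$t_end, by = dt)
  if (length(times) < 1) stop("empty time window", call. = FALSE)
  n_hold <- floor(spec$hold_ms / dt)
  if (n_hold > 0) times <- c(spec$t_start - dt * rev(seq_len(n_hold)), times)
  frames <- array(0, dim = c(geom$grid_h, geom$grid_w, length(times)))
  first <- render_frame(spec, geom, times[n_hold + 1])
  for (k in seq_along(times)) {
    frames[, , k] <- if (k <= n_hold) first else render_frame(spec, geom, times[k])
  }
  structure(
    list(frames = frames, times = times, theta = stimulus_theta(spec, times),
         dt = dt, geom = geom, spec = spec),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %dx%d, t = [%g, %g] ms (dt=%g)\n",
              dim(x$frames)[3], x$geom$grid_w, x$geom$grid_h,
              min(x$times), max(x$times), x$dt))
  invisible(x)
}

#' Add seeded Gaussian sensor noise to a frame sequence
#'
#' Emulates the trial-to-trial variability a physical camera introduces:
#' independent Gaussian noise per cell per frame, clipped back to the
#' `[0, 255]` luminance range. The same seed always yields the identical
#' sequence, so repetitions in an experiment are fully reproducible.
#'
#' @param seq a [render_sequence()] result.
#' @param sigma noise standard deviation in luminance units (>= 0).
#' @param seed integer seed.
#' @return a new `frame_sequence`.
#' @export
add_sensor_noise <- function(seq, sigma, seed) {
  if (!inherits(seq, "frame_sequence")) stop("'seq' must be a frame_sequence",
                                             call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (sigma == 0) return(seq)
  noisy <- with_seed(seed, seq$frames + stats::rnorm(length(seq$frames), 0, sigma))
  noisy[noisy < 0] <- 0
  noisy[noisy > 255] <- 255
  out <- seq
  out$frames <- noisy
  out
}

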