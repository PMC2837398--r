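# Rate estimation, peak / time-to-collision extraction, regressions, one-way
# ANOVA, and the scripted experiment protocols (speed, shape, approach-angle
# and inhibitory-gain sweeps).

#' Gaussian-kernel firing-rate estimate
#'
#' Convolves a spike train with a Gaussian kernel (sigma in ms, truncated at
#' +/- 3 sigma) and evaluates the result on a time grid, in Hz. The rate
#' integrates back to the spike count to within the truncation error (< 1%)
#' for spikes in the interior of the grid. An empty spike train gives a zero
#' trace, not an error.
#'
#' @param spikes spike times, ms (sorted or not).
#' @param t_grid evaluation grid, ms (uniformly spaced recommended).
#' @param sigma kernel standard deviation, ms (default 20 as in the standard
#'   LGMD analysis).
#' @return numeric vector of rates (Hz) on `t_grid`.
#' @examples
#' smooth_rate(c(0, 10, 20), seq(-100, 100, 1))
#' @export
smooth_rate <- function(spikes, t_grid, sigma = 20) {
  stopifnot(sigma > 0)
  out <- numeric(length(t_grid))
  if (length(spikes) == 0) return(out)
  spikes <- sort(spikes)
  for (s in spikes) {
    dtv <- t_grid - s
    idx <- abs(dtv) <= 3 * sigma
    # 1000 x: spike density per ms -> Hz
    out[idx] <- out[idx] + 1000 * stats::dnorm(dtv[idx], 0, sigma)
  }
  out
}

#' Locate the firing-rate peak
#'
#' Global maximum of a rate trace; on exact ties the earliest time wins.
#' An all-zero trace is reported as "no response" (`responded = FALSE`)
#' rather than an error.
#'
#' @param rate data frame with columns `time_ms` and `hz` (as in
#'   `lgmd_sim$rate`), or a numeric vector with `times` supplied separately.
#' @param times time grid, ms (only if `rate` is a bare vector).
#' @return list with `peak_time` (ms), `peak_rate` (Hz) and `responded`.
#' @export
extract_peak <- function(rate, times = NULL) {
  if (is.data.frame(rate)) {
    times <- rate$time_ms
    hz <- rate$hz
  } else hz <- rate
  if (length(hz) == 0) stop("empty rate trace", call. = FALSE)
  if (all(hz == 0))
    return(list(peak_time = NA_real_, peak_rate = 0, responded = FALSE))
  i <- which.max(hz)  # which.max returns the first (earliest) maximum
  list(peak_time = times[i], peak_rate = hz[i], responded = TRUE)
}

#' Regress time-to-collision on the l/|v| ratio
#'
#' Ordinary least-squares line through (l/|v|, TTC) points with the Pearson
#' correlation of the fit. The linearity of this relation, and the flattening
#' of its slope with growing angular threshold, are the core invariances the
#' network reproduces.
#'
#' @param lov l/|v| ratios, ms.
#' @param ttc times to collision of the rate peak, ms.
#' @return list with `slope`, `intercept` (ms) and `r`.
#' @export
regress_ttc <- function(lov, ttc) {
  ok <- is.finite(lov) & is.finite(ttc)
  lov <- lov[ok]; ttc <- ttc[ok]
  if (length(lov) < 3) stop("need at least 3 points for a TTC regression",
                            call. = FALSE)
  fit <- stats::lm(ttc ~ lov)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = safe_cor(lov, ttc))
}

#' Classic one-way ANOVA
#'
#' Fixed-effects one-way analysis of variance over two or more groups of
#' spike counts (or any numeric responses).
#'
#' @param groups list of numeric vectors, each with at least 2 values.
#' @return list with `F` and `p`.
#' @examples
#' anova_oneway(list(rnorm(10), rnorm(10, 2)))
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Experiment protocol specification
#'
#' Describes one of the standard stimulation protocols:
#' \describe{
#'   \item{`lov_sweep`}{looming solid square over a range of l/|v| ratios.}
#'   \item{`shape_sweep`}{the l/|v| sweep repeated for each stimulus shape.}
#'   \item{`angle_sweep`}{the sweep repeated at several approach-angle
#'     offsets.}
#'   \item{`receding_gain_sweep`}{a receding stimulus under several
#'     inhibitory gains.}
#'   \item{`uniform_expansion`}{an object growing linearly in angular size.}
#' }
#' Repetition-to-repetition variability comes solely from seeded sensor
#' noise (`noise_sigma`), so a protocol result is a pure function of the
#' spec and its seed.
#'
#' @param protocol protocol name (see above).
#' @param lov_values l/|v| ratios, ms (default 5 to 50 in steps of 5).
#' @param shapes stimulus shapes for `shape_sweep`.
#' @param angle_offsets approach-angle offsets (fraction of the half field)
#'   for `angle_sweep`.
#' @param inhibitory_gains `w_inh` values for `receding_gain_sweep`.
#' @param reps repetitions per condition (>= 1).
#' @param l object half-length, metres (fixed; the speed realises the ratio).
#' @param noise_sigma sensor noise s.d.; `NULL` takes the config's value.
#' @param align_jitter per-trial uniform jitter of the stimulus centre, in
#'   photoreceptor cells (default +/- 0.5). Emulates the trial-to-trial
#'   camera/screen alignment variability of a physical rig; without it the
#'   sub-cell alignment of the stimulus against the retinal raster is
#'   identical in every repetition and spike counts carry a spurious
#'   alignment signature.
#' @param base_config a [network_config()].
#' @param geom a [camera_geometry()].
#' @param seed top-level seed; per-trial seeds are derived from it.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol = c("lov_sweep", "shape_sweep", "angle_sweep",
                                       "receding_gain_sweep", "uniform_expansion"),
                          lov_values = seq(5, 50, by = 5),
                          shapes = c("solid_square", "concentric_squares",
                                     "checkerboard_square", "solid_circle"),
                          angle_offsets = c(0, 0.33, 0.55, 0.75),
                          inhibitory_gains = c(0.02, 0.01, 0.005, 0.001),
                          reps = 3L, l = 0.3, noise_sigma = NULL,
                          align_jitter = 0.5,
                          base_config = network_config(),
                          geom = camera_geometry(), seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(reps >= 1, all(lov_values > 0), l > 0, align_jitter >= 0)
  if (is.null(noise_sigma)) noise_sigma <- base_config$noise_sigma
  structure(
    list(protocol = protocol, lov_values = lov_values, shapes = shapes,
         angle_offsets = angle_offsets, inhibitory_gains = inhibitory_gains,
         reps = as.integer(reps), l = l, noise_sigma = noise_sigma,
         align_jitter = align_jitter,
         base_config = base_config, geom = geom, seed = as.integer(seed)),
    class = "protocol_spec")
}

# Metrics for one simulated trial.
trial_metrics <- function(sim) {
  pk <- extract_peak(sim$rate)
  theta_at_peak <- NA_real_
  ttc <- NA_real_
  if (pk$responded && sim$spec$mode == "looming") {
    ttc <- -pk$peak_time
    if (ttc > 0) theta_at_peak <- angular_size(sim$spec$l, sim$spec$v, ttc)
  }
  data.frame(peak_rate = pk$peak_rate,
             peak_time = if (pk$responded) pk$peak_time else NA_real_,
             ttc = ttc, theta_at_peak = theta_at_peak,
             spike_count = length(sim$spikes))
}

#' Run a full experiment protocol
#'
#' Renders the stimuli, runs the network once per trial (with seeded sensor
#' noise distinguishing repetitions), extracts per-trial metrics and
#' assembles per-condition summaries: TTC-vs-l/|v| regressions for the
#' looming sweeps and a one-way ANOVA over spike counts for the
#' approach-angle sweep.
#'
#' @param pspec a [protocol_spec()].
#' @param progress print one line per condition.
#' @return an object of class `lgmd_experiment`: list with `trials` (one row
#'   per trial), `regressions` (per condition group, where applicable),
#'   `anova` (angle sweep only), and `spec`.
#' @export
run_protocol <- function(pspec, progress = FALSE) {
  if (!inherits(pspec, "protocol_spec")) stop("'pspec' must be a protocol_spec",
                                              call. = FALSE)
  cfg <- pspec$base_config
  geom <- pspec$geom
  conditions <- switch(pspec$protocol,
    lov_sweep = data.frame(lov = pspec$lov_values, shape = "solid_square",
                           offset = 0, w_inh = cfg$w_inh,
                           stringsAsFactors = FALSE),
    shape_sweep = expand.grid(lov = pspec$lov_values, shape = pspec$shapes,
                              offset = 0, w_inh = cfg$w_inh,
                              stringsAsFactors = FALSE),
    angle_sweep = expand.grid(lov = pspec$lov_values, shape = "solid_square",
                              offset = pspec$angle_offsets, w_inh = cfg$w_inh,
                              stringsAsFactors = FALSE),
    receding_gain_sweep = data.frame(lov = 1000 * pspec$l / 10,
                                     shape = "solid_square", offset = 0,
                                     w_inh = pspec$inhibitory_gains,
                                     stringsAsFactors = FALSE),
    uniform_expansion = data.frame(lov = NA_real_, shape = "solid_square",
                                   offset = 0, w_inh = cfg$w_inh,
                                   stringsAsFactors = FALSE))
  rows <- list()
  trial_i <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    cfg_i <- cfg
    cfg_i$w_inh <- cond$w_inh
    sspec <- switch(pspec$protocol,
      receding_gain_sweep = looming_spec(shape = cond$shape, l = pspec$l, v = 10,
                                         mode = "receding"),
      uniform_expansion = looming_spec(shape = cond$shape, l = pspec$l, v = 10,
                                       mode = "uniform_expansion"),
      looming_spec(shape = cond$shape, l = pspec$l,
                   v = 1000 * pspec$l / cond$lov, angle_offset = cond$offset))
    seq0 <- if (pspec$align_jitter == 0) render_sequence(sspec, geom) else NULL
    for (rep_i in seq_len(pspec$reps)) {
      trial_i <- trial_i + 1L
      trial_seed <- derive_seed(pspec$seed, trial_i)
      if (is.null(seq0)) {
        # per-trial sub-cell alignment jitter of the stimulus centre
        jit <- with_seed(trial_seed + 1L,
                         stats::runif(1, -pspec$align_jitter,
                                      pspec$align_jitter))
        sspec_r <- sspec
        sspec_r$angle_offset <- max(0, sspec$angle_offset +
                                      jit * geom$px_w / (geom$fov_h / 2))
        seq_r <- render_sequence(sspec_r, geom)
      } else {
        seq_r <- seq0
      }
      seq_r <- add_sensor_noise(seq_r, pspec$noise_sigma, trial_seed)
      sim <- run_model(seq_r, cfg_i)
      m <- trial_metrics(sim)
      rows[[trial_i]] <- cbind(
        data.frame(condition = ci, lov = cond$lov, shape = cond$shape,
                   offset = cond$offset, w_inh = cond$w_inh, rep = rep_i,
                   stringsAsFactors = FALSE), m)
    }
    if (progress)
      message(sprintf("condition %d/%d done", ci, nrow(conditions)))
  }
  trials <- do.call(rbind, rows)

  regressions <- NULL
  if (pspec$protocol %in% c("lov_sweep", "shape_sweep", "angle_sweep")) {
    group_var <- switch(pspec$protocol, lov_sweep = NULL,
                        shape_sweep = "shape", angle_sweep = "offset")
    groups <- if (is.null(group_var)) list(all = trials)
              else split(trials, trials[[group_var]])
    regressions <- do.call(rbind, lapply(names(groups), function(g) {
      tr <- groups[[g]]
      # per-condition mean TTC, then regression on l/|v|
      mean_ttc <- tapply(tr$ttc, tr$lov, mean, na.rm = TRUE)
      lovs <- as.numeric(names(mean_ttc))
      if (sum(is.finite(as.numeric(mean_ttc))) < 3)
        return(data.frame(group = g, slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, stringsAsFactors = FALSE))
      rg <- regress_ttc(lovs, as.numeric(mean_ttc))
      data.frame(group = g, slope = rg$slope, intercept = rg$intercept,
                 r = rg$r, stringsAsFactors = FALSE)
    }))
  }

  anova <- NULL
  if (pspec$protocol == "angle_sweep") {
    counts <- split(trials$spike_count, trials$offset)
    if (length(counts) >= 2 && all(vapply(counts, length, 1L) >= 2))
      anova <- anova_oneway(counts)
  }

  structure(list(trials = trials, regressions = regressions, anova = anova,
                 spec = pspec),
            class = "lgmd_experiment")
}

#' @export
print.lgmd_experiment <- function(x, ...) {
  cat(sprintf("<lgmd_experiment> %s: %d trials\n", x$spec$protocol,
              nrow(x$trials)))
  if (!is.null(x$regressions)) {
    cat("TTC regressions:\n")
    print(x$regressions, row.names = FALSE)
  }
  if (!is.null(x$anova))
    cat(sprintf("one-way ANOVA on spike counts: F = %.3g, p = %.3g\n",
                x$anova$F, x$anova$p))
  invisible(x)
}
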