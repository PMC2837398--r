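# Calibration utility: scores candidate configurations against the
# invariant structure the network must satisfy (threshold constancy, TTC
# linearity, non-degenerate spiking). The shipped defaults were chosen with
# this scoring over a coarse grid.

#' Score or grid-search network calibrations
#'
#' Runs a reduced l/|v| sweep for each candidate configuration and scores it
#' on the model's structural invariants: the Pearson r of the TTC-vs-l/|v|
#' regression, the maximum deviation of the angular size at the rate peak
#' from the wiring threshold, and the number of silent (zero-spike) trials.
#' Use it to re-calibrate after changing the architecture or geometry.
#'
#' @param configs list of [network_config()] objects (named, ideally).
#' @param lov_values l/|v| ratios for the reduced sweep, ms.
#' @param reps repetitions per ratio.
#' @param geom a [camera_geometry()].
#' @param seed top-level seed.
#' @return data frame with one row per candidate: `name`, `ttc_r`,
#'   `max_theta_dev` (degrees), `zero_trials`, `mean_spikes`.
#' @examples
#' \donttest{
#' calibrate_network(list(default = network_config()),
#'                   lov_values = c(10, 30, 50), reps = 1)
#' }
#' @export
calibrate_network <- function(configs, lov_values = seq(10, 50, by = 10),
                              reps = 2, geom = camera_geometry(), seed = 1L) {
  stopifnot(is.list(configs), length(configs) > 0)
  if (is.null(names(configs)))
    names(configs) <- paste0("config_", seq_along(configs))
  rows <- lapply(names(configs), function(nm) {
    cfg <- configs[[nm]]
    theta_star <- unname(angular_threshold_estimate(cfg, geom)["x"])
    ps <- protocol_spec("lov_sweep", lov_values = lov_values, reps = reps,
                        base_config = cfg, geom = geom, seed = seed)
    res <- run_protocol(ps)
    tr <- res$trials
    mean_ttc <- tapply(tr$ttc, tr$lov, mean, na.rm = TRUE)
    lovs <- as.numeric(names(mean_ttc))
    ok <- is.finite(as.numeric(mean_ttc))
    ttc_r <- if (sum(ok) >= 3) regress_ttc(lovs[ok], as.numeric(mean_ttc)[ok])$r
             else NA_real_
    theta_at_peak <- 2 * atan(lovs / as.numeric(mean_ttc)) * 180 / pi
    data.frame(name = nm, ttc_r = ttc_r,
               max_theta_dev = suppressWarnings(
                 max(abs(theta_at_peak - theta_star), na.rm = TRUE)),
               zero_trials = sum(tr$spike_count == 0),
               mean_spikes = mean(tr$spike_count),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
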