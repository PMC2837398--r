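# Serialization: network configs as YAML (versioned schema, strict keys),
# simulation results as CSV, fits as JSON, frame sequences as PNG + JSON
# sidecar.

config_scalar_keys <- c("surround_weight", "onoff_delay", "delta_x", "delta_y",
                        "coincidence_threshold", "coincidence_rule",
                        "trail_extent", "lateral_weight", "fan_sample_extent",
                        "fanin_rule", "fan_leak", "chiasma_threshold",
                        "w_exc", "w_inh", "noise_sigma", "seed", "n_substeps")
config_layer_keys <- c("photo", "lamina", "medulla", "directional", "chiasma",
                       "lgmd")

#' Write a network configuration to a YAML file
#'
#' The file carries `schema_version: 1`; [read_network_config()] refuses
#' unknown keys so that calibrated defaults cannot be silently corrupted by
#' typos.
#'
#' @param config a [network_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_config <- function(config, path) {
  if (!inherits(config, "network_config")) stop("'config' must be a network_config",
                                                call. = FALSE)
  x <- list(schema_version = 1L)
  for (k in config_layer_keys) {
    p <- config[[k]]
    x[[k]] <- list(R = p$R, Cm = p$Cm, v_thresh = p$v_thresh, dt = p$dt,
                   mode = p$mode)
  }
  for (k in config_scalar_keys) x[[k]] <- config[[k]]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a network configuration from a YAML file
#'
#' @param path file written by [write_network_config()] (or by hand following
#'   the same schema).
#' @return a [network_config()].
#' @export
read_network_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$schema_version) || x$schema_version != 1L)
    stop("unsupported or missing schema_version (expected 1) in ", path,
         call. = FALSE)
  known <- c("schema_version", config_layer_keys, config_scalar_keys)
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (k in config_layer_keys) {
    if (is.null(x[[k]])) next
    lp <- x[[k]]
    bad <- setdiff(names(lp), c("R", "Cm", "v_thresh", "dt", "mode"))
    if (length(bad) > 0)
      stop("unknown key(s) in layer '", k, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    args[[k]] <- neuron_params(R = lp$R, Cm = lp$Cm, v_thresh = lp$v_thresh,
                               dt = lp$dt, mode = lp$mode)
  }
  for (k in config_scalar_keys) if (!is.null(x[[k]])) args[[k]] <- x[[k]]
  do.call(network_config, args)
}

#' Export a simulation result as CSV files
#'
#' Writes `spikes.csv` (`time_ms`), `rate.csv` (`time_ms`, `hz`) and
#' `layers.csv` (`time_ms` plus one column of mean activity per layer and
#' the LGMD input currents) into `dir`.
#'
#' @param sim an [run_model()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation_result <- function(sim, dir) {
  if (!inherits(sim, "lgmd_sim")) stop("'sim' must be an lgmd_sim", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time_ms = sim$spikes),
                   file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(sim$rate, file.path(dir, "rate.csv"), row.names = FALSE)
  utils::write.csv(cbind(sim$layers, vm = sim$vm),
                   file.path(dir, "layers.csv"), row.names = FALSE)
  invisible(dir)
}

#' Export a fit result as JSON
#'
#' @param fit a [fit_multiplicative()] or [fit_linear_mapping()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  x <- if (inherits(fit, "fit_result")) {
    list(model = "multiplicative",
         params = list(alpha = fit$params$alpha, delta = fit$params$delta,
                       gain = fit$params$gain, mapping = fit$params$mapping),
         r = fit$r, residual_rms = fit$residual_rms)
  } else if (inherits(fit, "linear_mapping_fit")) {
    list(model = "linear_mapping", intercept = fit$intercept,
         weights = fit$weights, r = fit$r, residual_rms = fit$residual_rms)
  } else stop("unsupported fit object", call. = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a frame sequence as PNG files plus a JSON sidecar
#'
#' Frames become numbered 8-bit grayscale PNGs (`frame_0001.png`, ...) and
#' `sequence.json` records the time base and geometry. Requires the `png`
#' package.
#'
#' @param seq a [render_sequence()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frame_sequence <- function(seq, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  if (!inherits(seq, "frame_sequence")) stop("'seq' must be a frame_sequence",
                                             call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(seq$frames)[3]
  for (k in seq_len(n))
    png::writePNG(seq$frames[, , k] / 255,
                  file.path(dir, sprintf("frame_%04d.png", k)))
  meta <- list(n_frames = n, dt = seq$dt, t0 = seq$times[1],
               times = seq$times, theta = seq$theta,
               geometry = list(fov_h = seq$geom$fov_h, fov_v = seq$geom$fov_v,
                               grid_w = seq$geom$grid_w,
                               grid_h = seq$geom$grid_h,
                               deg_per_pixel = seq$geom$deg_per_pixel))
  jsonlite::write_json(meta, file.path(dir, "sequence.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame sequence written by [write_frame_sequence()]
#'
#' @param dir directory with `frame_*.png` and `sequence.json`.
#' @return a `frame_sequence` (with `spec = NULL`).
#' @export
read_frame_sequence <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG import", call. = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "sequence.json"),
                              simplifyVector = TRUE)
  g <- meta$geometry
  geom <- camera_geometry(fov_h = g$fov_h, fov_v = g$fov_v, grid_w = g$grid_w,
                          grid_h = g$grid_h, deg_per_pixel = g$deg_per_pixel)
  frames <- array(0, dim = c(g$grid_h, g$grid_w, meta$n_frames))
  for (k in seq_len(meta$n_frames)) {
    img <- png::readPNG(file.path(dir, sprintf("frame_%04d.png", k)))
    if (length(dim(img)) == 3) img <- img[, , 1]
    frames[, , k] <- img * 255
  }
  structure(list(frames = frames, times = meta$times, theta = meta$theta,
                 dt = meta$dt, geom = geom, spec = NULL),
            class = "frame_sequence")
}
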