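# Leaky linear-threshold (LT) and leaky integrate-and-fire (I&F) units.
#
# Both primitives are the classic parallel RC circuit driven by a current:
#   C dV/dt = -V/R + I  <=>  dV/dt = -V/tau + I/C,  tau = R * C.
# An LT unit outputs its membrane potential once it exceeds threshold; an
# I&F unit emits a spike at threshold and resets the membrane to zero.
# Everything downstream in the network is built from these two units, so
# the only nonlinearity anywhere in the pathway is thresholding.

#' Neuron parameters
#'
#' Parameter set for a leaky linear-threshold (`"LT"`) or leaky
#' integrate-and-fire (`"IAF"`) unit modelled as a parallel RC circuit.
#' The membrane time constant is always `tau = R * Cm`; supply any two of
#' `R`, `Cm` and the third is implied (both must be given, `tau` is derived).
#'
#' @param R membrane resistance (arbitrary consistent units).
#' @param Cm membrane capacitance (arbitrary consistent units).
#' @param v_thresh firing/output threshold, in the same (arbitrary) voltage
#'   units as the membrane potential. Must be >= 0.
#' @param dt integration step in ms. The network simulator uses one step per
#'   video frame (10 ms at 100 frames/s) unless sub-stepping is requested.
#' @param mode `"LT"` (graded output above threshold) or `"IAF"`
#'   (spike-and-reset).
#' @return an object of class `neuron_params`.
#' @examples
#' p <- neuron_params(R = 1, Cm = 10, v_thresh = 1, dt = 10, mode = "IAF")
#' p$tau  # 10 ms
#' @export
neuron_params <- function(R = 1, Cm = 10, v_thresh = 0, dt = 10,
                          mode = c("LT", "IAF")) {
  mode <- match.arg(mode)
  for (nm in c("R", "Cm", "dt")) stop_if_not_scalar(get(nm), nm)
  # v_thresh = Inf is a valid "never fires / pure integrator" setting
  if (!is.numeric(v_thresh) || length(v_thresh) != 1L || is.na(v_thresh))
    stop("'v_thresh' must be a numeric scalar", call. = FALSE)
  if (R <= 0 || Cm <= 0) stop("'R' and 'Cm' must be positive", call. = FALSE)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (v_thresh < 0) stop("'v_thresh' must be >= 0", call. = FALSE)
  structure(
    list(R = R, Cm = Cm, tau = R * Cm, v_thresh = v_thresh, dt = dt,
         mode = mode),
    class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> %s: R=%g Cm=%g tau=%g ms v_thresh=%g dt=%g ms\n",
              x$mode, x$R, x$Cm, x$tau, x$v_thresh, x$dt))
  invisible(x)
}

#' Advance a neuron (or a grid of identical neurons) by one time step
#'
#' One forward-Euler step of `dV/dt = -V/tau + I/Cm` over `params$dt`,
#' followed by the mode's output rule. For `"LT"` the output equals the
#' membrane potential wherever it is at or above threshold and is zero
#' elsewhere. For `"IAF"` a spike (output 1) is emitted wherever threshold is
#' reached and the membrane is reset to exactly zero there.
#'
#' `vm` and `input_current` may be scalars, vectors or matrices of matching
#' shape; a whole retinotopic layer is advanced in one call.
#'
#' @param state list with element `vm` (membrane potential), as returned by
#'   a previous call, or `NULL` for a resting (vm = 0) start.
#' @param params a [neuron_params()] object.
#' @param input_current driving current, same shape as `state$vm`.
#' @return list with elements `vm` (updated potential) and `output`
#'   (graded activity for LT, 0/1 spike indicator for IAF).
#' @examples
#' p <- neuron_params(R = 1, Cm = 10, v_thresh = 0, dt = 1, mode = "LT")
#' s <- neuron_step(NULL, p, input_current = 2)
#' @export
neuron_step <- function(state, params, input_current) {
  if (!inherits(params, "neuron_params"))
    stop("'params' must be a neuron_params object", call. = FALSE)
  if (!is.numeric(input_current) || any(!is.finite(input_current)))
    stop("'input_current' must be finite numeric", call. = FALSE)
  vm <- if (is.null(state)) input_current * 0 else state$vm
  vm <- vm + params$dt * (-vm / params$tau + input_current / params$Cm)
  if (params$mode == "LT") {
    output <- vm
    output[vm < params$v_thresh] <- 0
  } else {
    fired <- vm >= params$v_thresh
    output <- fired * 1
    vm[fired] <- 0
  }
  list(vm = vm, output = output)
}

#' Analytic RC charging curve
#'
#' Closed-form membrane potential of the leaky unit under a constant input
#' current, starting from rest: `V(t) = I * R * (1 - exp(-t / tau))`. The
#' voltage rises asymptotically to `I * R`. Used as the exact oracle against
#' which the discrete [neuron_step()] trajectory is checked.
#'
#' @param params a [neuron_params()] object.
#' @param input_current constant driving current.
#' @param t time since current onset, ms (>= 0; vectorised).
#' @return membrane potential at time `t`.
#' @examples
#' p <- neuron_params(R = 1, Cm = 10)
#' charge_curve(p, 10, t = 10)  # 10 * (1 - exp(-1))
#' @export
charge_curve <- function(params, input_current, t) {
  if (!inherits(params, "neuron_params"))
    stop("'params' must be a neuron_params object", call. = FALSE)
  stop_if_not_scalar(input_current, "input_current")
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be non-negative", call. = FALSE)
  input_current * params$R * (1 - exp(-t / params$tau))
}

#' Inter-spike interval of the ideal continuous-time integrate-and-fire unit
#'
#' For a constant suprathreshold current the continuous-time I&F fires
#' periodically with period `T = -tau * log(1 - v_thresh / (I * R))`.
#' Simulated spike trains approach the rate `1/T` as the integration step
#' shrinks. Subthreshold currents (`I * R <= v_thresh`) never fire; this is
#' reported as an infinite period rather than an error.
#'
#' @param params a [neuron_params()] object (mode `"IAF"` expected).
#' @param input_current constant driving current.
#' @return period in ms, or `Inf` if the unit never fires.
#' @examples
#' p <- neuron_params(R = 1, Cm = 10, v_thresh = 1, mode = "IAF")
#' iaf_period(p, 2)  # 10 * log(2)
#' @export
iaf_period <- function(params, input_current) {
  if (!inherits(params, "neuron_params"))
    stop("'params' must be a neuron_params object", call. = FALSE)
  stop_if_not_scalar(input_current, "input_current")
  ir <- input_current * params$R
  if (ir <= params$v_thresh) return(Inf)
  -params$tau * log(1 - params$v_thresh / ir)
}
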