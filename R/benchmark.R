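# Phenomenological comparison models of the LGMD:
#   * the multiplicative (eta) model,
#       f(t) = gain * g( theta'(t - delta) * exp(-alpha * theta(t - delta)) ),
#     which peaks at a fixed angular size theta* = 2 * atan(1 / alpha) and
#     whose peak time is t_peak = alpha * l/|v| - delta before collision;
#   * the second derivative of the angular size, theta''(t); and
#   * a multivariate least-squares linear mapping from raw (sub-sampled)
#     input frames to the firing rate.
# These are fitted to (or compared against) the network model's rate traces.

#' Multiplicative-model parameters
#'
#' @param alpha size-decay constant, 1/radians (> 0). The implied angular
#'   threshold is `2 * atan(1/alpha)` (radians).
#' @param delta response latency, ms (>= 0).
#' @param gain output scaling to Hz.
#' @param mapping monotone output nonlinearity: `"linear"` (identity above
#'   zero, default) or `"exponential"` (`exp(beta * eta) - 1`, the
#'   membrane-to-rate mapping through which the multiplication is realised as
#'   an exponential of summed log inputs). Peak-location properties do not
#'   depend on this choice.
#' @param beta exponent scale of the exponential mapping, in units of
#'   1/(rad/ms) (ignored by the linear mapping). Larger values concentrate
#'   the predicted firing into a sharper burst around the eta peak.
#' @return an object of class `multiplicative_params`.
#' @export
multiplicative_params <- function(alpha, delta = 0, gain = 1,
                                  mapping = c("linear", "exponential"),
                                  beta = 500) {
  mapping <- match.arg(mapping)
  stopifnot(alpha > 0, delta >= 0, is.finite(gain), beta > 0)
  structure(list(alpha = alpha, delta = delta, gain = gain, mapping = mapping,
                 beta = beta),
            class = "multiplicative_params")
}

#' @export
print.multiplicative_params <- function(x, ...) {
  cat(sprintf("<multiplicative_params> alpha=%.4g /rad, delta=%.4g ms, gain=%.4g (%s); theta*=%.2f deg\n",
              x$alpha, x$delta, x$gain, x$mapping,
              2 * atan(1 / x$alpha) * 180 / pi))
  invisible(x)
}

# Shift a uniformly sampled trace later in time by delta ms (linear
# interpolation, clamped at the ends).
shift_trace <- function(x, times, delta) {
  if (delta == 0) return(x)
  stats::approx(times, x, xout = times - delta, rule = 2)$y
}

#' Multiplicative (eta) model trace
#'
#' Evaluates `eta(t) = theta'(t - delta) * exp(-alpha * theta(t - delta))`
#' on a uniformly sampled angular-size trace (theta converted to radians
#' internally, theta' by central differences) and applies the output mapping
#' and gain. For constant theta the output is identically zero; for a
#' constant expansion rate it is proportional to `exp(-alpha * theta(t))`, a
#' monotonically decaying trace — the signature that distinguishes this
#' model from the network.
#'
#' @param theta angular-size trace, degrees.
#' @param times uniform time grid, ms.
#' @param params a [multiplicative_params()].
#' @return rate trace (same length as `theta`).
#' @export
eta_trace <- function(theta, times, params) {
  if (!inherits(params, "multiplicative_params"))
    stop("'params' must be multiplicative_params", call. = FALSE)
  if (length(theta) < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(theta) != length(times)) stop("length mismatch", call. = FALSE)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
    stop("'times' must be uniformly sampled", call. = FALSE)
  th <- shift_trace(theta, times, params$delta) * pi / 180
  n <- length(th)
  dth <- c(th[2] - th[1], (th[3:n] - th[1:(n - 2)]) / 2, th[n] - th[n - 1]) / dt[1]
  eta <- dth * exp(-params$alpha * th)
  out <- switch(params$mapping,
                linear = rect(eta),
                exponential = rect(exp(params$beta * eta) - 1))
  params$gain * out
}

#' Fit the multiplicative model to a firing-rate trace
#'
#' Least-squares fit of `(alpha, delta, gain)` — plus the exponent scale
#' `beta` when `mapping = "exponential"`: the gain is profiled out in closed
#' form, and the remaining parameters are found by a coarse grid search
#' refined with Nelder-Mead. Reports the Pearson correlation between the
#' fitted and the target trace. On data generated by the model itself the
#' parameters are recovered essentially exactly.
#'
#' @param target_rate target firing-rate trace, Hz.
#' @param theta angular-size trace, degrees, aligned with `target_rate`.
#' @param times uniform time grid, ms.
#' @param mapping output nonlinearity passed to [multiplicative_params()].
#' @param delta_grid,alpha_grid,beta_grid search grids for the coarse stage
#'   (`beta_grid` is used by the exponential mapping only).
#' @return an object of class `fit_result`: list with `params`
#'   (fitted [multiplicative_params()]), `fitted` (trace), `r`,
#'   `residual_rms` (Hz).
#' @export
fit_multiplicative <- function(target_rate, theta, times,
                               mapping = c("linear", "exponential"),
                               delta_grid = seq(0, 60, by = 5),
                               alpha_grid = exp(seq(log(0.5), log(20),
                                                    length.out = 25)),
                               beta_grid = c(100, 300, 1000, 3000, 10000)) {
  mapping <- match.arg(mapping)
  if (all(target_rate == 0)) stop("degenerate all-zero target", call. = FALSE)
  stopifnot(length(target_rate) == length(theta),
            length(theta) == length(times))
  if (mapping == "linear") beta_grid <- 1
  sse_of <- function(alpha, delta, beta) {
    tr <- eta_trace(theta, times,
                    multiplicative_params(alpha, delta, 1, mapping, beta))
    if (any(!is.finite(tr))) return(Inf)
    denom <- sum(tr^2)
    g <- if (denom > 0) sum(tr * target_rate) / denom else 0
    sum((target_rate - g * tr)^2)
  }
  best <- NULL
  for (d in delta_grid) for (a in alpha_grid) for (b in beta_grid) {
    s <- sse_of(a, d, b)
    if (is.null(best) || s < best$sse)
      best <- list(alpha = a, delta = d, beta = b, sse = s)
  }
  # latency is bounded by the physiological range; beta kept finite so the
  # exponential mapping cannot degenerate into a delta spike
  opt <- stats::optim(c(log(best$alpha), best$delta, log(best$beta)),
                      function(p) {
                        if (p[2] < 0 || p[2] > 200 || p[3] > log(1e6))
                          return(Inf)
                        sse_of(exp(p[1]), p[2], exp(p[3]))
                      }, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-10))
  alpha <- exp(opt$par[1]); delta <- max(0, opt$par[2]); beta <- exp(opt$par[3])
  tr <- eta_trace(theta, times,
                  multiplicative_params(alpha, delta, 1, mapping, beta))
  denom <- sum(tr^2)
  gain <- if (denom > 0) sum(tr * target_rate) / denom else 0
  fitted <- gain * tr
  structure(
    list(params = multiplicative_params(alpha, delta, gain, mapping, beta),
         fitted = fitted, r = safe_cor(fitted, target_rate),
         residual_rms = sqrt(mean((target_rate - fitted)^2))),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> r = %.4f, residual RMS = %.3g Hz\n",
              x$r, x$residual_rms))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Second derivative of the angular size
#'
#' `theta''(t)` by second central differences, optionally normalised to unit
#' peak for comparison with (normalised) firing-rate traces. A linear
#' angular-size trace maps to identically zero.
#'
#' @param theta angular-size trace, degrees.
#' @param times uniform time grid, ms.
#' @param normalize divide by the maximum absolute value (if nonzero).
#' @return trace of the same length (deg/ms^2, or unit peak).
#' @export
second_derivative_trace <- function(theta, times, normalize = TRUE) {
  n <- length(theta)
  if (n < 5) stop("need at least 5 samples", call. = FALSE)
  stopifnot(length(times) == n)
  dt <- times[2] - times[1]
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (theta[3:n] - 2 * theta[2:(n - 1)] + theta[1:(n - 2)]) / dt^2
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  if (normalize && max(abs(d2)) > 0) d2 <- d2 / max(abs(d2))
  d2
}

# Area-averaging resampling matrix from n source cells to m target cells:
# entry [j, i] is the fraction of target bin j covered by source cell i.
resample_weights <- function(n, m) {
  wgt <- matrix(0, m, n)
  ratio <- n / m
  for (j in seq_len(m)) {
    lo <- (j - 1) * ratio; hi <- j * ratio
    for (i in seq_len(n)) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) wgt[j, i] <- ov / ratio
    }
  }
  wgt
}

#' Fit a multivariate linear input-output mapping
#'
#' Ordinary least squares from raw input frames (sub-sampled to
#' `sub_h x sub_w` cells by area averaging) plus an intercept to the firing
#' rate sampled at the frame times:
#' `rate(t) ~ w0 + sum_ij w_ij * pixel_ij(t)`.
#' Pixels that are constant across the sequence are dropped before solving;
#' residual collinearity is handled by a tiny ridge penalty with a warning.
#' Such a mapping reproduces looming responses in-sample but, being blind to
#' motion direction, fails to generalise to receding stimuli — use
#' [predict_linear_mapping()] on a held-out sequence to see the failure.
#'
#' @param seq a [render_sequence()] result (the raw stimulus frames).
#' @param target_rate firing rate at the frame times, Hz (same length as the
#'   number of frames).
#' @param sub_w,sub_h sub-sampled frame size (default 16 x 14).
#' @return an object of class `linear_mapping_fit`: list with `weights`
#'   (`sub_h x sub_w` matrix, zeros for dropped pixels), `intercept`,
#'   `fitted`, `r`, `residual_rms`, and the resampling geometry.
#' @export
fit_linear_mapping <- function(seq, target_rate, sub_w = 16L, sub_h = 14L) {
  if (!inherits(seq, "frame_sequence")) stop("'seq' must be a frame_sequence",
                                             call. = FALSE)
  n <- dim(seq$frames)[3]
  if (length(target_rate) != n)
    stop("frame count and trace length differ", call. = FALSE)
  X <- subsample_design(seq, sub_w, sub_h)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  Xk <- X[, keep, drop = FALSE]
  Xc <- cbind(1, Xk)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    warning("rank-deficient design; using a tiny ridge penalty")
    lambda <- 1e-8 * sum(diag(crossprod(Xc))) / ncol(Xc)
    beta <- solve(crossprod(Xc) + diag(lambda, ncol(Xc)), crossprod(Xc, target_rate))
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrX, target_rate)
  }
  w <- matrix(0, sub_h, sub_w)
  w[keep] <- beta[-1]
  fitted <- drop(Xc %*% beta)
  structure(
    list(weights = w, intercept = beta[1], keep = keep,
         sub_w = as.integer(sub_w), sub_h = as.integer(sub_h),
         fitted = fitted, r = safe_cor(fitted, target_rate),
         residual_rms = sqrt(mean((target_rate - fitted)^2))),
    class = "linear_mapping_fit")
}

# T x (sub_h * sub_w) design matrix of area-averaged frames.
subsample_design <- function(seq, sub_w, sub_h) {
  h <- dim(seq$frames)[1]; w <- dim(seq$frames)[2]; n <- dim(seq$frames)[3]
  A <- resample_weights(h, sub_h)
  B <- t(resample_weights(w, sub_w))
  t(vapply(seq_len(n), function(k) as.vector(A %*% seq$frames[, , k] %*% B),
           numeric(sub_h * sub_w)))
}

#' Predict a firing rate from frames with a fitted linear mapping
#'
#' @param fit a [fit_linear_mapping()] result.
#' @param seq a [render_sequence()] result.
#' @return predicted rate at the frame times.
#' @export
predict_linear_mapping <- function(fit, seq) {
  if (!inherits(fit, "linear_mapping_fit")) stop("'fit' must be a linear_mapping_fit",
                                                 call. = FALSE)
  X <- subsample_design(seq, fit$sub_w, fit$sub_h)
  drop(fit$intercept + X %*% as.vector(fit$weights))
}
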