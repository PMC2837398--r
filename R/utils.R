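# Internal helpers: grid shifts, small convolutions, seed management.

#' Shift a matrix with zero fill
#'
#' Moves the contents of `m` by `dr` rows (positive = down) and `dc` columns
#' (positive = right); cells shifted in from outside the grid are zero.
#' @param m numeric matrix.
#' @param dr,dc integer displacements.
#' @return matrix of the same dimension.
#' @keywords internal
#' @noRd
shift_grid <- function(m, dr = 0L, dc = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  if (abs(dr) >= h || abs(dc) >= w) return(out)
  sr <- max(1L, 1L + dr):min(h, h + dr)
  sc <- max(1L, 1L + dc):min(w, w + dc)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

# 3x3 convolution, kernel indexed [row, col] with the centre at [2, 2].
# pad = "zero" assumes silence outside the grid; pad = "replicate" extends
# the border values, so a uniform field stays uniform under a zero-sum
# kernel (no spurious border response). Implemented as shift-and-add; grids
# here are tiny (tens of cells a side) so this is faster than FFT routes.
conv3x3 <- function(m, kernel, pad = c("zero", "replicate")) {
  stopifnot(all(dim(kernel) == c(3L, 3L)))
  pad <- match.arg(pad)
  if (pad == "replicate") {
    h <- nrow(m); w <- ncol(m)
    mp <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
    out <- matrix(0, h, w)
    for (i in -1:1) for (j in -1:1) {
      k <- kernel[i + 2L, j + 2L]
      if (k != 0) out <- out + k * mp[seq_len(h) + 1 - i, seq_len(w) + 1 - j]
    }
    return(out)
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (i in -1:1) {
    for (j in -1:1) {
      k <- kernel[i + 2L, j + 2L]
      if (k != 0) out <- out + k * shift_grid(m, i, j)
    }
  }
  out
}

# Sum of the 8 nearest neighbours of every cell (zero padding).
neighbour_sum <- function(m) {
  k <- matrix(1, 3, 3); k[2, 2] <- 0
  conv3x3(m, k)
}

#' Derive a per-trial seed from a top-level seed
#'
#' All stochastic components take their seed from one top-level integer via
#' this map, so that a whole experiment is reproducible from a single number.
#' Kept strictly below 2^31 so the result is a valid R integer seed.
#' @param seed top-level integer seed.
#' @param i trial index (>= 1).
#' @return integer seed.
#' @export
derive_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + i * 16807) %% 2147483629)
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Rectify: max(x, 0), elementwise.
rect <- function(x) {
  x[x < 0] <- 0
  x
}

# Pearson correlation that tolerates zero-variance inputs (returns 0).
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

stop_if_not_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
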