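# Internal helpers shared across modules.

#' Pixel-centre coordinates of a centred grid axis
#'
#' Pixels are indexed 0-based with centres at `(i + 0.5) * pixel_size`,
#' shifted so the grid is centred on the origin (the ring-array centre).
#'
#' @param n number of pixels along the axis
#' @param pixel_size pixel pitch in metres
#' @param center coordinate of the grid centre in metres
#' @return numeric vector of `n` coordinates in metres
#' @export
grid_coords <- function(n, pixel_size, center = 0) {
  (seq_len(n) - 0.5 - n / 2) * pixel_size + center
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
}

# Zero-phase frequency-domain filter. `gain_fun` maps |f| in Hz to a real
# gain in [0, 1]; applied symmetrically so the impulse response is real and
# the phase identically zero (no arrival-time shift).
fft_filter <- function(x, sampling_rate, gain_fun) {
  n <- length(x)
  f <- seq(0, n - 1) / n * sampling_rate
  f <- pmin(f, sampling_rate - f) # two-sided |f|
  g <- gain_fun(f)
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

# Raised-cosine (Tukey-edged) band gain: unity on [f1, f2], cosine rolls
# over widths w1 (below f1) and w2 (above f2), zero outside.
raised_cosine_gain <- function(f, f1, f2, w1, w2) {
  g <- numeric(length(f))
  g[f >= f1 & f <= f2] <- 1
  if (w1 > 0) {
    lo <- f >= (f1 - w1) & f < f1
    g[lo] <- 0.5 * (1 + cos(pi * (f1 - f[lo]) / w1))
  }
  if (w2 > 0) {
    hi <- f > f2 & f <= (f2 + w2)
    g[hi] <- 0.5 * (1 + cos(pi * (f[hi] - f2) / w2))
  }
  g
}

# Central-difference time derivative along a vector; one-sided at the ends.
time_derivative <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

# Deposit weights w at fractional sample positions s (1-based, may be
# fractional) into a vector of length n by linear two-sample splitting.
deposit_linear <- function(s, w, n) {
  i0 <- floor(s)
  frac <- s - i0
  idx <- c(i0, i0 + 1)
  val <- c(w * (1 - frac), w * frac)
  keep <- idx >= 1 & idx <= n
  out <- numeric(n)
  if (any(keep)) {
    acc <- rowsum(val[keep], idx[keep])
    out[as.integer(rownames(acc))] <- acc[, 1]
  }
  out
}
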