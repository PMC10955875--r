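# Trace-level processing: filtering, wavelet denoising, SNR, envelopes,
# time-of-flight picking, sound-speed regression, frame averaging.

#' Zero-phase low-pass filter
#'
#' Frequency-domain low-pass with unity gain up to `cutoff`, raised-cosine
#' roll-off over `roll * cutoff`, and zero gain beyond — so attenuation at
#' 1.5x the cutoff is effectively complete, and the phase is identically
#' zero (no group delay).
#'
#' @param trace numeric vector
#' @param cutoff cutoff frequency, Hz
#' @param sampling_rate Hz
#' @param roll fractional transition width (default 0.25)
#' @return filtered trace
#' @export
lowpass <- function(trace, cutoff, sampling_rate, roll = 0.25) {
  stop_if_not_finite(trace, "trace")
  nyq <- sampling_rate / 2
  if (cutoff >= nyq) stop("cutoff must be below Nyquist", call. = FALSE)
  fft_filter(trace, sampling_rate,
             function(f) raised_cosine_gain(f, 0, cutoff, 0, roll * cutoff))
}

#' Wavelet denoising specification
#'
#' Coiflet wavelet shrinkage with the universal ("sqtwolog") threshold
#' `sigma_hat * sqrt(2 log N)`, `sigma_hat` estimated per detail level from
#' the median absolute deviation, applied translation-invariantly by
#' averaging over `shifts` circular shifts (cycle spinning).
#'
#' @param order Coiflet order, 1-3 (default 3)
#' @param levels decomposition levels (default 6)
#' @param thresholding `"hard"` (default) or `"soft"` shrinkage of detail
#'   coefficients; hard keeps the amplitude of in-band signal
#'   coefficients intact, soft shrinks them by the threshold
#' @param shifts number of circular shifts averaged for translation
#'   invariance (default 16; 1 disables cycle spinning)
#' @return an object of class `eat_denoise_spec`
#' @export
denoise_spec <- function(order = 3, levels = 6,
                         thresholding = c("hard", "soft"), shifts = 16) {
  thresholding <- match.arg(thresholding)
  if (levels < 1) stop("levels must be >= 1", call. = FALSE)
  if (shifts < 1) stop("shifts must be >= 1", call. = FALSE)
  structure(list(order = order, levels = levels, thresholding = thresholding,
                 shifts = as.integer(shifts)),
            class = "eat_denoise_spec")
}

denoise_once <- function(x, spec) {
  w <- dwt(x, spec$levels, spec$order)
  lambda <- sqrt(2 * log(length(x)))
  for (j in seq_along(w$details)) {
    d <- w$details[[j]]
    sigma_hat <- mad(d, center = 0) # median(|d|)/0.6745, noise sd estimate
    thr <- sigma_hat * lambda
    if (spec$thresholding == "soft") {
      w$details[[j]] <- sign(d) * pmax(abs(d) - thr, 0)
    } else {
      d[abs(d) < thr] <- 0
      w$details[[j]] <- d
    }
  }
  idwt(w)
}

#' Wavelet denoising with the universal threshold
#'
#' Decomposes the trace with a periodized Coiflet DWT, thresholds each
#' detail level at `sigma_hat_j * sqrt(2 log N)` where `sigma_hat_j` is the
#' MAD-based noise estimate of that level's coefficients and `N` the trace
#' length, reconstructs, and averages over circular shifts for translation
#' invariance.  The approximation band is left untouched.  On a noise-free
#' trace the estimated thresholds collapse towards zero and the round trip
#' is near-lossless.
#'
#' Traces whose length is not divisible by `2^levels` are symmetrically
#' padded at the end for the transform and truncated back afterwards.
#'
#' @param trace numeric vector with at least `2^levels` samples
#' @param spec an [denoise_spec()]
#' @return denoised trace, same length as the input
#' @export
wavelet_denoise <- function(trace, spec = denoise_spec()) {
  stop_if_not_finite(trace, "trace")
  stopifnot(inherits(spec, "eat_denoise_spec"))
  n <- length(trace)
  block <- 2^spec$levels
  if (n < block) stop("trace shorter than 2^levels", call. = FALSE)
  n_pad <- ceiling(n / block) * block
  x <- if (n_pad > n) {
    c(trace, rev(trace)[seq_len(n_pad - n)]) # symmetric tail extension
  } else {
    trace
  }
  m <- length(x)
  acc <- numeric(m)
  for (k in seq_len(spec$shifts) - 1L) {
    xs <- x[((seq_len(m) - 1 + k) %% m) + 1]
    ds <- denoise_once(xs, spec)
    acc <- acc + ds[((seq_len(m) - 1 - k) %% m) + 1]
  }
  (acc / spec$shifts)[seq_len(n)]
}

#' Signal-to-noise ratio of a trace
#'
#' `20 log10( max|trace[signal_window]| / sd(trace[noise_window]) )`: peak
#' signal amplitude over noise standard deviation, in dB.
#'
#' @param trace numeric vector
#' @param signal_window integer indices of the signal region
#' @param noise_window integer indices of a signal-free region
#' @return SNR in dB
#' @export
compute_snr <- function(trace, signal_window, noise_window) {
  if (length(signal_window) == 0 || length(noise_window) == 0) {
    stop("windows must be non-empty", call. = FALSE)
  }
  if (length(intersect(signal_window, noise_window)) > 0) {
    stop("signal and noise windows must be disjoint", call. = FALSE)
  }
  s <- max(abs(trace[signal_window]))
  n <- sd(trace[noise_window])
  if (n == 0) stop("noise window has zero standard deviation", call. = FALSE)
  20 * log10(s / n)
}

# SNR of a denoised/noisy trace against a known clean reference.
residual_snr <- function(trace, clean) {
  20 * log10(max(abs(clean)) / sd(trace - clean))
}

#' Analytic-signal envelope
#'
#' Magnitude of the analytic signal (Hilbert transform quadrature), the
#' standard envelope detector for RF ultrasound traces.
#'
#' @param trace numeric vector
#' @return non-negative envelope, same length
#' @export
envelope <- function(trace) {
  stop_if_not_finite(trace, "trace")
  analytic_envelope(trace)
}

# FFT analytic-signal magnitude (internal; also used by recon where a
# function argument named `envelope` shadows the exported name).
analytic_envelope <- function(trace) {
  n <- length(trace)
  if (n == 0) return(numeric(0))
  X <- fft(trace)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Time-of-flight estimation
#'
#' Default picker returns the time of the envelope maximum (sub-sample by
#' parabolic interpolation); the `"threshold"` picker returns the first
#' crossing of `threshold_frac` times the envelope maximum.  Returns `NA`
#' with a "no arrival" note when no sample exceeds `detection` (absolute
#' envelope units).
#'
#' @param trace numeric vector (RF trace; envelope is computed internally)
#' @param sampling_rate Hz
#' @param t0 absolute time of the first sample, seconds
#' @param method `"peak"` (default) or `"threshold"`
#' @param threshold_frac fraction of the envelope maximum for the
#'   threshold picker (default 0.5)
#' @param detection minimum envelope amplitude for a valid arrival
#' @return arrival time in seconds, or `NA_real_` if no arrival detected
#' @export
estimate_tof <- function(trace, sampling_rate, t0 = 0,
                         method = c("peak", "threshold"),
                         threshold_frac = 0.5, detection = 0) {
  method <- match.arg(method)
  env <- envelope(trace)
  if (length(env) == 0 || max(env) <= detection || max(env) == 0) {
    return(NA_real_)
  }
  if (method == "peak") {
    k <- which.max(env)
    # parabolic sub-sample refinement
    if (k > 1 && k < length(env)) {
      y1 <- env[k - 1]; y2 <- env[k]; y3 <- env[k + 1]
      denom <- y1 - 2 * y2 + y3
      delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
      k <- k + max(min(delta, 0.5), -0.5)
    }
  } else {
    thr <- threshold_frac * max(env)
    k <- which(env >= thr)[1]
    if (k > 1) { # linear interpolation onto the crossing
      k <- (k - 1) + (thr - env[k - 1]) / (env[k] - env[k - 1])
    }
  }
  t0 + (k - 1) / sampling_rate
}

#' Sound-speed regression from distance / time-of-flight pairs
#'
#' Ordinary least squares of distance on TOF: `d = a + c t`.  The slope `c`
#' is the propagation speed; `-a / c` is the time intercept (instrumental
#' delay).
#'
#' @param distances metres
#' @param tofs seconds
#' @return list with `speed` (m/s), `intercept_time` (s),
#'   `intercept_distance` (m), `r_squared`, and the fitted `model`
#' @examples
#' fit_sound_speed(c(30e-3, 55e-3), c(20.8e-6, 37.5e-6))$speed # ~1497
#' @export
fit_sound_speed <- function(distances, tofs) {
  stopifnot(length(distances) == length(tofs))
  if (length(distances) < 2) stop("need at least 2 points", call. = FALSE)
  if (length(unique(tofs)) < 2) {
    stop("degenerate fit: all TOFs identical", call. = FALSE)
  }
  fit <- lm(distances ~ tofs)
  cf <- coef(fit)
  speed <- unname(cf[2])
  # exact synthetic data fits perfectly; the summary.lm warning is benign
  r2 <- if (length(distances) > 2) {
    suppressWarnings(summary(fit)$r.squared)
  } else {
    1
  }
  list(
    speed = speed,
    intercept_time = unname(-cf[1] / speed),
    intercept_distance = unname(cf[1]),
    r_squared = r2,
    model = fit
  )
}

#' Frame stack container
#'
#' A sequence of channel-data frames acquired at a fixed interval,
#' `n_frames x elements x samples`.
#'
#' @param frames 3-D array `n_frames x elements x samples`
#' @param frame_interval seconds between frames
#' @param sampling_rate per-trace sampling rate, Hz
#' @param meta provenance list
#' @return an object of class `eat_frame_stack`
#' @export
frame_stack <- function(frames, frame_interval, sampling_rate = NA_real_,
                        meta = list()) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[1] >= 1, frame_interval > 0)
  structure(
    list(frames = frames, frame_interval = frame_interval,
         sampling_rate = sampling_rate, meta = meta),
    class = "eat_frame_stack"
  )
}

#' @export
print.eat_frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<eat_frame_stack> %d frames x %d elements x %d samples, %.3g ms interval\n",
    d[1], d[2], d[3], x$frame_interval * 1e3
  ))
  invisible(x)
}

#' Average adjacent frames
#'
#' Non-overlapping blocks of `k` consecutive frames are averaged, reducing
#' white-noise standard deviation by `sqrt(k)`: 3000 raw frames at 1 ms
#' intervals averaged in blocks of 10 give a 300-frame stack at 10 ms
#' effective temporal resolution.  A trailing remainder (when `n_frames`
#' is not divisible by `k`) is dropped with a warning.
#'
#' @param stack an [frame_stack()]
#' @param k block size (>= 1)
#' @return averaged [frame_stack()] with `floor(n/k)` frames and
#'   `k * frame_interval` spacing
#' @export
frame_average <- function(stack, k) {
  stopifnot(inherits(stack, "eat_frame_stack"))
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == 1) return(stack)
  d <- dim(stack$frames)
  n_out <- d[1] %/% k
  if (n_out == 0) stop("fewer frames than block size", call. = FALSE)
  if (d[1] %% k != 0) {
    warning(sprintf("dropping %d trailing frame(s) not filling a block of %d",
                    d[1] %% k, k))
  }
  out <- array(0, c(n_out, d[2], d[3]))
  for (b in seq_len(n_out)) {
    block <- stack$frames[((b - 1) * k + 1):(b * k), , , drop = FALSE]
    out[b, , ] <- colMeans(block, dims = 1)
  }
  frame_stack(out, stack$frame_interval * k, stack$sampling_rate,
              meta = c(stack$meta, list(averaged_k = k)))
}

#' Evenly spaced display frames from a video
#'
#' Picks `n_display` frames evenly covering a stack of duration
#' `n_frames * frame_interval`, the convention used for showing a handful
#' of stills from a reconstruction video: 8 frames from a 3 s, 300-frame
#' video fall at 375 ms spacing, the first at t = 375 ms.
#'
#' @param n_frames total frames available
#' @param frame_interval seconds per frame
#' @param n_display number of frames to display
#' @return data.frame with `index` (1-based frame index) and `time`
#'   (seconds, end-of-frame convention)
#' @export
display_frames <- function(n_frames, frame_interval, n_display = 8) {
  stopifnot(n_display >= 1, n_frames >= n_display)
  idx <- round(seq_len(n_display) * n_frames / n_display)
  data.frame(index = idx, time = seq_len(n_display) * n_frames * frame_interval / n_display)
}
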