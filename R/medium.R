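#' Gridded material maps for a 2-D tissue domain
#'
#' A `medium` bundles the material property maps that drive both the
#' electrical and the acoustic halves of the model on a common square-pixel
#' grid: electrical conductivity `sigma`, thermal expansion coefficient
#' `beta`, isothermal compressibility `kappa`, mass density `rho`, specific
#' heat capacity `c_v`, and speed of sound `v_s`.  Scalars are recycled into
#' full maps.  All quantities are SI.
#'
#' The grid lies in the plane of the ring array, with the origin at the
#' array centre and pixel centres at `(i + 0.5) * pixel_size` offsets
#' (0-based pixel indices); see [grid_coords()].
#'
#' @param grid_shape integer vector `c(nx, ny)`
#' @param pixel_size pixel pitch, metres
#' @param sigma electrical conductivity, S/m (map or scalar)
#' @param beta thermal expansion coefficient, 1/K
#' @param kappa isothermal compressibility, 1/Pa
#' @param rho mass density, kg/m^3
#' @param c_v specific heat capacity, J/(kg K)
#' @param v_s speed of sound, m/s (a single value is used for propagation)
#' @return an object of class `eat_medium`: a list of the validated maps
#'   plus `grid_shape` and `pixel_size`
#' @examples
#' med <- medium(c(64, 64), 0.5e-3, sigma = 0.5)
#' range(med$sigma)
#' @seealso [muscle_medium()] for tissue-typical defaults
#' @export
medium <- function(grid_shape, pixel_size,
                   sigma = 0.5, beta = 4e-4, kappa = 4.5e-10,
                   rho = 1050, c_v = 3600, v_s = 1497) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 2L)) {
    stop("grid_shape must be two integers >= 2", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a positive scalar", call. = FALSE)
  }
  as_map <- function(x, name) {
    if (length(x) == 1L) x <- matrix(x, grid_shape[1], grid_shape[2])
    x <- as.matrix(x)
    if (!identical(dim(x), grid_shape)) {
      stop(name, " map does not match grid_shape", call. = FALSE)
    }
    stop_if_not_finite(x, name)
    x
  }
  m <- structure(
    list(
      grid_shape = grid_shape, pixel_size = pixel_size,
      sigma = as_map(sigma, "sigma"), beta = as_map(beta, "beta"),
      kappa = as_map(kappa, "kappa"), rho = as_map(rho, "rho"),
      c_v = as_map(c_v, "c_v"), v_s = as_map(v_s, "v_s")
    ),
    class = "eat_medium"
  )
  if (any(m$sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (any(m$rho <= 0)) stop("rho must be > 0", call. = FALSE)
  if (any(m$c_v <= 0)) stop("c_v must be > 0", call. = FALSE)
  if (any(m$v_s <= 0)) stop("v_s must be > 0", call. = FALSE)
  if (any(m$kappa <= 0)) stop("kappa must be > 0", call. = FALSE)
  m
}

#' Muscle-like homogeneous medium
#'
#' Convenience constructor with property values typical of skeletal muscle /
#' soft tissue at room temperature: sigma 0.5 S/m, beta 4e-4 1/K, kappa
#' 4.5e-10 1/Pa, rho 1050 kg/m^3, c_v 3600 J/(kg K) and the sound speed
#' measured for the electroacoustic wave in saline-like media, 1497 m/s.
#'
#' @inheritParams medium
#' @param ... overrides passed on to [medium()]
#' @return an `eat_medium`
#' @export
muscle_medium <- function(grid_shape, pixel_size, ...) {
  medium(grid_shape, pixel_size, ...)
}

#' @export
print.eat_medium <- function(x, ...) {
  cat(sprintf(
    "<eat_medium> %d x %d pixels, %.3g mm pitch (%.1f x %.1f mm)\n",
    x$grid_shape[1], x$grid_shape[2], x$pixel_size * 1e3,
    x$grid_shape[1] * x$pixel_size * 1e3, x$grid_shape[2] * x$pixel_size * 1e3
  ))
  cat(sprintf(
    "  sigma [%.3g, %.3g] S/m; v_s [%.4g, %.4g] m/s\n",
    min(x$sigma), max(x$sigma), min(x$v_s), max(x$v_s)
  ))
  invisible(x)
}

#' Two-disc electrode pair
#'
#' Two circular electrodes (exposed tip footprints rasterized onto the
#' medium grid) in either of the polarity configurations used for
#' electroporation delivery: `"1p1g"` (one electrode driven at `voltage`,
#' the other grounded) or `"2p"` (both driven at `voltage`; the grounded
#' outer boundary of the solve domain provides the return path).
#'
#' @param centers 2x2 matrix (or list of two length-2 vectors) of electrode
#'   centre coordinates in metres
#' @param radius disc radius, metres (scalar, both electrodes)
#' @param mode `"1p1g"` or `"2p"`
#' @param voltage applied pulse amplitude, volts
#' @param voltages optional explicit per-electrode potentials (length 2,
#'   volts) overriding the `mode` mapping; used e.g. for a symmetric
#'   `c(+V/2, -V/2)` drive
#' @return an object of class `eat_electrodes` with fields `centers`,
#'   `radius`, `gap` (edge-to-edge distance), `mode`, `voltage`,
#'   `potentials`
#' @examples
#' ep <- electrode_pair(rbind(c(-2.5e-3, 0), c(2.5e-3, 0)),
#'                      radius = 0.5e-3, mode = "1p1g", voltage = 1000)
#' ep$gap # 4 mm
#' @export
electrode_pair <- function(centers, radius, mode = c("1p1g", "2p"),
                           voltage = 0, voltages = NULL) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- matrix(as.numeric(centers), 2, 2)
  mode <- match.arg(mode)
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  d <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  gap <- d - 2 * radius
  if (gap <= 0) stop("electrode discs overlap or touch (gap <= 0)", call. = FALSE)
  potentials <- if (!is.null(voltages)) {
    stopifnot(length(voltages) == 2L)
    as.numeric(voltages)
  } else if (mode == "1p1g") c(voltage, 0) else c(voltage, voltage)
  structure(
    list(centers = centers, radius = radius, gap = gap, mode = mode,
         voltage = voltage, potentials = potentials),
    class = "eat_electrodes"
  )
}

#' @export
print.eat_electrodes <- function(x, ...) {
  cat(sprintf(
    "<eat_electrodes> mode %s, %g V; tips r = %.3g mm at (%.2f, %.2f) / (%.2f, %.2f) mm, gap %.3g mm\n",
    x$mode, x$voltage, x$radius * 1e3,
    x$centers[1, 1] * 1e3, x$centers[1, 2] * 1e3,
    x$centers[2, 1] * 1e3, x$centers[2, 2] * 1e3, x$gap * 1e3
  ))
  invisible(x)
}

#' Nanosecond pulse waveform description
#'
#' Describes the near-square high-voltage excitation pulse: amplitude,
#' full-width-at-half-maximum `width`, linear `rise_time` (fall assumed
#' equal), and repetition rate.  The effective energy-deposition time
#' [tau_eff()] is the integral of the normalized squared voltage waveform.
#'
#' @param amplitude pulse amplitude, volts
#' @param width FWHM of the pulse, seconds (default 100 ns)
#' @param rise_time 10-90-style linear rise, seconds (default 15 ns)
#' @param rep_rate repetition rate, Hz
#' @return an object of class `eat_pulse`
#' @export
pulse_waveform <- function(amplitude, width = 100e-9, rise_time = 15e-9,
                           rep_rate = 1000) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  if (rise_time < 0 || rise_time >= width) {
    stop("rise_time must be in [0, width)", call. = FALSE)
  }
  if (rep_rate < 0) stop("rep_rate must be >= 0", call. = FALSE)
  structure(
    list(amplitude = amplitude, width = width, rise_time = rise_time,
         rep_rate = rep_rate),
    class = "eat_pulse"
  )
}

#' Effective pulse width for Joule-heating dose
#'
#' Integral of the normalized squared voltage waveform.  For a trapezoid
#' with FWHM `width` and linear edges of duration `rise_time` this is
#' `width - rise_time / 3`; for a 100 ns / 15 ns pulse, 95 ns — close to
#' the FWHM, as expected for a near-square pulse.
#'
#' @param pulse an [pulse_waveform()] object
#' @return effective width in seconds
#' @export
tau_eff <- function(pulse) {
  stopifnot(inherits(pulse, "eat_pulse"))
  pulse$width - pulse$rise_time / 3
}
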