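# Image formation: universal filtered back-projection (primary) and
# delay-and-sum (cross-check oracle).

#' Reconstruction grid description
#'
#' A square-pixel image grid in the array plane, by default concentric
#' with the ring.  Pixel centres follow the same 0-based
#' `(i + 0.5) * pixel_size` convention as the medium grid.
#'
#' @param nx,ny image size in pixels
#' @param pixel_size metres
#' @param center grid centre in metres (default the ring centre, origin)
#' @return an object of class `eat_grid` with coordinate vectors `x`, `y`
#' @export
recon_grid <- function(nx, ny, pixel_size, center = c(0, 0)) {
  stopifnot(nx >= 1, ny >= 1, pixel_size > 0)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), pixel_size = pixel_size,
         center = center,
         x = grid_coords(nx, pixel_size, center[1]),
         y = grid_coords(ny, pixel_size, center[2])),
    class = "eat_grid"
  )
}

#' Reconstructed image container
#'
#' @param pixels matrix nx x ny
#' @param grid the [recon_grid()] the image lives on
#' @param normalization `"none"` or `"max1"`
#' @param provenance list describing algorithm and parameters
#' @return an object of class `eat_image`
#' @export
recon_image <- function(pixels, grid, normalization = "none", provenance = list()) {
  stop_if_not_finite(pixels, "pixels")
  structure(
    list(pixels = pixels, grid = grid, normalization = normalization,
         provenance = provenance),
    class = "eat_image"
  )
}

#' @export
print.eat_image <- function(x, ...) {
  cat(sprintf(
    "<eat_image> %d x %d px @ %.3g mm (%s), range [%.3g, %.3g]\n",
    x$grid$nx, x$grid$ny, x$grid$pixel_size * 1e3,
    if (length(x$provenance$algorithm)) x$provenance$algorithm else "unknown",
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

# Shared back-projector: per detector, sample a prepared per-channel
# signal at the pixel arrival times (linear interpolation) and accumulate
# with uniform element weights.
backproject <- function(signals, data, v_s, grid) {
  geo <- data$geometry
  fs <- data$sampling_rate
  n_s <- ncol(signals)
  img <- matrix(0, grid$nx, grid$ny)
  pxm <- matrix(grid$x, grid$nx, grid$ny)
  pym <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  for (j in seq_len(geo$n_elements)) {
    d <- sqrt((pxm - geo$positions[j, 1])^2 + (pym - geo$positions[j, 2])^2)
    s <- (d / v_s - data$t0) * fs + 1
    i0 <- floor(s)
    frac <- s - i0
    ok <- i0 >= 1 & i0 < n_s
    v <- matrix(0, grid$nx, grid$ny)
    sig <- signals[j, ]
    v[ok] <- sig[i0[ok]] * (1 - frac[ok]) + sig[i0[ok] + 1] * frac[ok]
    img <- img + v
  }
  img / geo$n_elements
}

check_recon_inputs <- function(data, v_s, grid) {
  stopifnot(inherits(data, "eat_channel_data"), inherits(grid, "eat_grid"))
  if (!is.numeric(v_s) || v_s <= 0) stop("v_s must be > 0", call. = FALSE)
  rmax <- sqrt(max(grid$x^2) + max(grid$y^2))
  if (rmax > data$geometry$ring_radius) {
    stop("reconstruction grid extends outside the detector ring", call. = FALSE)
  }
}

#' Universal back-projection reconstruction
#'
#' Filtered back-projection for a full-view ring array: each channel is
#' turned into the back-projection term `b(t) = 2 p(t) - 2 t dp/dt`
#' (time derivative by central differences, `t` the absolute arrival time)
#' and projected onto circular shells `t = |r - r0| / v_s`, summed over
#' elements with uniform aperture weights.  With `envelope = TRUE` the
#' analytic-signal magnitude of `b(t)` is projected instead, giving the
#' non-negative display images conventional for ring-array tomography.
#'
#' @param data an [channel_data()]
#' @param v_s reconstruction sound speed, m/s (same uniform speed as the
#'   forward model; speed mismatch is deliberately not modelled)
#' @param grid an [recon_grid()] inside the ring
#' @param envelope project envelope-detected signals (default FALSE)
#' @return an [recon_image()]
#' @export
ubp_reconstruct <- function(data, v_s, grid, envelope = FALSE) {
  check_recon_inputs(data, v_s, grid)
  fs <- data$sampling_rate
  n_s <- ncol(data$traces)
  tt <- data$t0 + (seq_len(n_s) - 1) / fs
  b <- matrix(0, nrow(data$traces), n_s)
  for (j in seq_len(nrow(b))) {
    p <- data$traces[j, ]
    b[j, ] <- 2 * p - 2 * tt * time_derivative(p, 1 / fs)
    if (envelope) b[j, ] <- analytic_envelope(b[j, ])
  }
  img <- backproject(b, data, v_s, grid)
  recon_image(img, grid,
              provenance = list(algorithm = "ubp", v_s = v_s,
                                envelope = envelope))
}

#' Delay-and-sum reconstruction
#'
#' Plain coherent delay-and-sum of the (optionally envelope-detected)
#' traces onto the grid; retained as an independent beamforming cross-check
#' for the filtered back-projection.
#'
#' @inheritParams ubp_reconstruct
#' @return an [recon_image()]
#' @export
das_reconstruct <- function(data, v_s, grid, envelope = FALSE) {
  check_recon_inputs(data, v_s, grid)
  sig <- data$traces
  if (envelope) sig <- t(apply(sig, 1, analytic_envelope))
  img <- backproject(sig, data, v_s, grid)
  recon_image(img, grid,
              provenance = list(algorithm = "das", v_s = v_s,
                                envelope = envelope))
}

#' Normalize a reconstructed image
#'
#' `"max1"` divides by the global maximum absolute pixel value so images
#' taken under different drive conditions can be compared on one scale; an
#' all-zero image is returned unchanged.
#'
#' @param image an [recon_image()]
#' @param mode `"max1"` or `"none"`
#' @return normalized [recon_image()]
#' @export
normalize_image <- function(image, mode = c("max1", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "eat_image"))
  if (mode == "none") return(image)
  m <- max(abs(image$pixels))
  if (m > 0) image$pixels <- image$pixels / m
  image$normalization <- "max1"
  image
}

#' Peak position of a reconstructed image
#'
#' Pixel-grid coordinates (metres) and indices of the maximum absolute
#' pixel, the standard point-target localization readout.
#'
#' @param image an [recon_image()]
#' @return list with `ix`, `iy` (1-based indices) and `x`, `y` (metres)
#' @export
image_peak <- function(image) {
  stopifnot(inherits(image, "eat_image"))
  k <- which.max(abs(image$pixels))
  ix <- ((k - 1) %% image$grid$nx) + 1
  iy <- ((k - 1) %/% image$grid$nx) + 1
  list(ix = ix, iy = iy, x = image$grid$x[ix], y = image$grid$y[iy],
       value = image$pixels[k])
}

#' Intensity-weighted centroid of the bright region
#'
#' Centroid of pixels at or above `threshold_frac` of the image maximum —
#' a sub-pixel target localizer far more robust to noise than the bare
#' argmax.
#'
#' @param image an [recon_image()]
#' @param threshold_frac fraction of the maximum defining the bright
#'   region (default 0.5)
#' @return list with `x`, `y` (metres)
#' @export
image_centroid <- function(image, threshold_frac = 0.5) {
  stopifnot(inherits(image, "eat_image"))
  px <- image$pixels
  m <- max(px)
  if (m <= 0) return(list(x = NA_real_, y = NA_real_))
  w <- px * (px >= threshold_frac * m)
  xs <- matrix(image$grid$x, image$grid$nx, image$grid$ny)
  ys <- matrix(image$grid$y, image$grid$nx, image$grid$ny, byrow = TRUE)
  list(x = sum(w * xs) / sum(w), y = sum(w * ys) / sum(w))
}
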