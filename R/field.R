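# Quasi-static electric field, Joule dose and initial pressure.
#
# The potential solve is a 5-point finite-difference discretization of
# div(sigma grad phi) = 0 with conductivity-weighted (harmonic-mean) face
# conductances, Dirichlet values on the rasterized electrode discs and a
# grounded outer boundary.  The sparse SPD system is solved by a direct
# sparse Cholesky factorization and the discrete residual is verified
# against `tol`.

# Logical mask of pixels whose centre lies inside a disc.
rasterize_disc <- function(grid_shape, pixel_size, center, radius) {
  x <- grid_coords(grid_shape[1], pixel_size)
  y <- grid_coords(grid_shape[2], pixel_size)
  outer(x, y, function(xx, yy) (xx - center[1])^2 + (yy - center[2])^2 <= radius^2)
}

#' Solve the quasi-static potential for an electrode pair
#'
#' Solves the discrete conservation law `div(sigma grad phi) = 0` on the
#' medium grid with the electrode discs held at their applied potentials
#' and the outer boundary grounded (`phi = 0`), emulating a conductive bath
#' much larger than the electrode gap.  In the `"2p"` polarity mode the
#' grounded boundary is also the current return path.
#'
#' Face conductances between neighbouring pixels are harmonic means of the
#' pixel conductivities, so insulating inclusions (`sigma = 0`) are handled
#' without special casing.  The resulting SPD system is solved by sparse
#' Cholesky; the relative residual of the interior equations is checked
#' against `tol` and the solve fails loudly if it is not met.
#'
#' @param medium an [medium()] object
#' @param electrodes an [electrode_pair()] object
#' @param boundary `"square"` grounds the rectangular domain edge;
#'   `"circle"` additionally grounds everything outside the largest
#'   inscribed circle (useful when comparing with closed-form solutions in
#'   a circular bath)
#' @param tol relative residual tolerance for the accepted solution
#' @return matrix `nx x ny` of potentials in volts
#' @examples
#' med <- medium(c(81, 81), 0.5e-3)
#' ep <- electrode_pair(rbind(c(-2e-3, 0), c(2e-3, 0)), 0.6e-3,
#'                      mode = "1p1g", voltage = 100)
#' phi <- solve_potential(med, ep)
#' max(phi) # 100 on the driven electrode
#' @export
solve_potential <- function(medium, electrodes, boundary = c("square", "circle"),
                            tol = 1e-8) {
  stopifnot(inherits(medium, "eat_medium"), inherits(electrodes, "eat_electrodes"))
  boundary <- match.arg(boundary)
  nx <- medium$grid_shape[1]
  ny <- medium$grid_shape[2]
  h <- medium$pixel_size

  disc1 <- rasterize_disc(medium$grid_shape, h, electrodes$centers[1, ], electrodes$radius)
  disc2 <- rasterize_disc(medium$grid_shape, h, electrodes$centers[2, ], electrodes$radius)
  if (!any(disc1) || !any(disc2)) {
    stop("an electrode disc rasterizes to zero pixels; refine the grid", call. = FALSE)
  }
  if (any(disc1 & disc2)) stop("electrode discs overlap on the grid", call. = FALSE)

  x <- grid_coords(nx, h)
  y <- grid_coords(ny, h)
  half_x <- nx * h / 2
  half_y <- ny * h / 2
  for (k in 1:2) {
    c_k <- electrodes$centers[k, ]
    if (abs(c_k[1]) + electrodes$radius >= half_x ||
        abs(c_k[2]) + electrodes$radius >= half_y) {
      stop("electrode disc extends outside the domain", call. = FALSE)
    }
  }

  dirichlet <- matrix(FALSE, nx, ny)
  dir_val <- matrix(0, nx, ny)
  dirichlet[1, ] <- TRUE; dirichlet[nx, ] <- TRUE
  dirichlet[, 1] <- TRUE; dirichlet[, ny] <- TRUE
  if (boundary == "circle") {
    rb <- min(half_x, half_y) - h / 2
    outside <- outer(x, y, function(xx, yy) xx^2 + yy^2 >= rb^2)
    dirichlet[outside] <- TRUE
  }
  dirichlet[disc1] <- TRUE; dir_val[disc1] <- electrodes$potentials[1]
  dirichlet[disc2] <- TRUE; dir_val[disc2] <- electrodes$potentials[2]

  idx <- matrix(0L, nx, ny)
  free <- !dirichlet
  n_free <- sum(free)
  if (n_free == 0L) return(dir_val)
  idx[free] <- seq_len(n_free)

  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  sig <- medium$sigma
  # face conductances between (i,j) and (i+1,j) / (i,j+1)
  gx <- harm(sig[-nx, ], sig[-1, ])   # (nx-1) x ny
  gy <- harm(sig[, -ny], sig[, -1])   # nx x (ny-1)

  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_acc <- numeric(n_free)
  b <- numeric(n_free)

  add_faces <- function(ia, ja, ib, jb, g) {
    # connects pixel a=(ia,ja) to b=(ib,jb) with conductance g (vectors)
    fa <- free[cbind(ia, ja)]; fb <- free[cbind(ib, jb)]
    ka <- idx[cbind(ia, ja)]; kb <- idx[cbind(ib, jb)]
    both <- fa & fb & g > 0
    if (any(both)) {
      rows <<- c(rows, ka[both], kb[both])
      cols <<- c(cols, kb[both], ka[both])
      vals <<- c(vals, -g[both], -g[both])
    }
    a_only <- fa & g > 0
    if (any(a_only)) {
      acc <- rowsum(g[a_only], ka[a_only])
      diag_acc[as.integer(rownames(acc))] <<- diag_acc[as.integer(rownames(acc))] + acc[, 1]
    }
    b_only <- fb & g > 0
    if (any(b_only)) {
      acc <- rowsum(g[b_only], kb[b_only])
      diag_acc[as.integer(rownames(acc))] <<- diag_acc[as.integer(rownames(acc))] + acc[, 1]
    }
    a_dir_b <- fb & !fa & g > 0 # a is Dirichlet, feeds b
    if (any(a_dir_b)) {
      acc <- rowsum(g[a_dir_b] * dir_val[cbind(ia, ja)][a_dir_b], kb[a_dir_b])
      b[as.integer(rownames(acc))] <<- b[as.integer(rownames(acc))] + acc[, 1]
    }
    b_dir_a <- fa & !fb & g > 0
    if (any(b_dir_a)) {
      acc <- rowsum(g[b_dir_a] * dir_val[cbind(ib, jb)][b_dir_a], ka[b_dir_a])
      b[as.integer(rownames(acc))] <<- b[as.integer(rownames(acc))] + acc[, 1]
    }
  }

  ii <- rep(seq_len(nx - 1), ny); jj <- rep(seq_len(ny), each = nx - 1)
  add_faces(ii, jj, ii + 1L, jj, as.vector(gx))
  ii <- rep(seq_len(nx), ny - 1); jj <- rep(seq_len(ny - 1), each = nx)
  add_faces(ii, jj, ii, jj + 1L, as.vector(gy))

  # pixels with no conductive connection: pin to 0 to keep the system SPD
  diag_acc[diag_acc == 0] <- 1

  A <- Matrix::sparseMatrix(
    i = c(rows, seq_len(n_free)), j = c(cols, seq_len(n_free)),
    x = c(vals, diag_acc), dims = c(n_free, n_free)
  )
  phi_free <- as.numeric(Matrix::solve(A, b))

  resid <- as.numeric(A %*% phi_free - b)
  scale <- max(sqrt(sum(b^2)), max(abs(electrodes$potentials)), .Machine$double.eps)
  rel <- sqrt(sum(resid^2)) / scale
  if (!is.finite(rel) || rel > tol) {
    stop(sprintf("potential solve did not reach tolerance: relative residual %.3g > %.3g",
                 rel, tol), call. = FALSE)
  }

  phi <- dir_val
  phi[free] <- phi_free
  phi
}

#' Electric field from a potential map
#'
#' `E = -grad(phi)` by central differences on the interior and one-sided
#' differences on the domain edge.
#'
#' @param potential matrix of potentials, volts
#' @param pixel_size pixel pitch, metres
#' @return list with components `ex`, `ey` (V/m) and `mag = sqrt(ex^2+ey^2)`
#' @export
e_field <- function(potential, pixel_size) {
  nx <- nrow(potential); ny <- ncol(potential)
  ex <- matrix(0, nx, ny); ey <- matrix(0, nx, ny)
  ex[1, ] <- -(potential[2, ] - potential[1, ]) / pixel_size
  ex[nx, ] <- -(potential[nx, ] - potential[nx - 1, ]) / pixel_size
  ex[2:(nx - 1), ] <- -(potential[3:nx, ] - potential[1:(nx - 2), ]) / (2 * pixel_size)
  ey[, 1] <- -(potential[, 2] - potential[, 1]) / pixel_size
  ey[, ny] <- -(potential[, ny] - potential[, ny - 1]) / pixel_size
  ey[, 2:(ny - 1)] <- -(potential[, 3:ny] - potential[, 1:(ny - 2)]) / (2 * pixel_size)
  list(ex = ex, ey = ey, mag = sqrt(ex^2 + ey^2))
}

#' Nominal (plate-approximation) field strength label
#'
#' The voltage-over-gap figure conventionally used to label pulsed-field
#' exposures, e.g. 1200 V across a 5 mm gap is quoted as 2.4 kV/cm.
#'
#' @param voltage applied voltage, volts
#' @param gap electrode gap, metres
#' @param units `"V_per_m"` or `"kV_per_cm"`
#' @return field strength in the requested units
#' @examples
#' nominal_field_strength(1200, 5e-3, "kV_per_cm") # 2.4
#' @export
nominal_field_strength <- function(voltage, gap, units = c("V_per_m", "kV_per_cm")) {
  units <- match.arg(units)
  if (!is.numeric(gap) || any(gap <= 0)) stop("gap must be > 0", call. = FALSE)
  e <- voltage / gap
  if (units == "kV_per_cm") e / 1e5 else e
}

#' Joule energy deposition per pulse
#'
#' `H(r) = sigma(r) |E(r)|^2 tau_eff`, the per-pulse Joule heat density in
#' J/m^3, with `tau_eff` the effective (squared-waveform) pulse width.
#'
#' @param e_field output of [e_field()], or a matrix of field magnitudes in
#'   V/m
#' @param medium an [medium()] (supplies `sigma`)
#' @param pulse an [pulse_waveform()]; alternatively pass `tau` directly
#' @param tau effective pulse width in seconds (overrides `pulse`)
#' @return dose map H, J/m^3
#' @export
energy_deposition <- function(e_field, medium, pulse = NULL, tau = NULL) {
  stopifnot(inherits(medium, "eat_medium"))
  mag <- if (is.list(e_field)) e_field$mag else e_field
  if (!identical(dim(mag), dim(medium$sigma))) {
    stop("e_field is not on the medium grid", call. = FALSE)
  }
  if (any(medium$sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(tau)) {
    if (is.null(pulse)) stop("supply either pulse or tau", call. = FALSE)
    tau <- tau_eff(pulse)
  }
  medium$sigma * mag^2 * tau
}

#' Initial acoustic pressure from an energy-deposition map
#'
#' `p0(r) = beta(r) / (kappa(r) rho(r) c_v(r)) * H(r)`: under stress and
#' thermal confinement the deposited heat density converts to pressure via
#' the Grueneisen-like factor of the medium.
#'
#' @param dose dose map H, J/m^3
#' @param medium an [medium()]
#' @return initial pressure map, Pa
#' @export
initial_pressure <- function(dose, medium) {
  stopifnot(inherits(medium, "eat_medium"))
  if (!identical(dim(dose), dim(medium$beta))) {
    stop("dose is not on the medium grid", call. = FALSE)
  }
  if (any(medium$kappa == 0) || any(medium$rho == 0) || any(medium$c_v == 0)) {
    stop("kappa, rho and c_v must be nonzero everywhere", call. = FALSE)
  }
  medium$beta / (medium$kappa * medium$rho * medium$c_v) * dose
}

#' Full electrical-to-acoustic source solution
#'
#' Convenience wrapper running [solve_potential()], [e_field()],
#' [energy_deposition()] and [initial_pressure()] in sequence.
#'
#' @inheritParams solve_potential
#' @param pulse an [pulse_waveform()]
#' @param ... passed to [solve_potential()]
#' @return an object of class `eat_field`: list with `potential`, `ex`,
#'   `ey`, `e_mag`, `dose`, `p0`, and the inputs
#' @export
field_solution <- function(medium, electrodes, pulse, ...) {
  phi <- solve_potential(medium, electrodes, ...)
  ef <- e_field(phi, medium$pixel_size)
  dose <- energy_deposition(ef, medium, pulse)
  p0 <- initial_pressure(dose, medium)
  structure(
    list(potential = phi, ex = ef$ex, ey = ef$ey, e_mag = ef$mag,
         dose = dose, p0 = p0, medium = medium, electrodes = electrodes,
         pulse = pulse),
    class = "eat_field"
  )
}
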