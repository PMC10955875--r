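# Shared fixtures: analytic waveforms and small phantoms, built in code.

# Bipolar N-shaped test pulse (derivative-of-Gaussian), peak amplitude 1.
# centre_freq is the spectral peak of the DoG.
make_nwave <- function(n, sampling_rate, t_center, center_freq = 4e6) {
  t <- (seq_len(n) - 1) / sampling_rate
  w <- 1 / (2 * pi * center_freq)
  u <- (t - t_center) / w
  s <- -u * exp(-u^2 / 2)
  s / max(abs(s))
}

# Fractional pixel coverage rasterization of a disc (anti-aliased).
cover_disc <- function(xs, pixel_size, radius, ss = 4) {
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  M <- matrix(0, length(xs), length(xs))
  for (ox in off) {
    for (oy in off) {
      M <- M + outer(xs + ox * pixel_size, xs + oy * pixel_size,
                     function(a, b) (a^2 + b^2 <= radius^2) + 0)
    }
  }
  M / ss^2
}

# Closed-form retarded shell integral for a uniform unit disc (radius R0 at
# the origin) observed at distance D0: p(t) = 2 theta(r) v_s / (4 pi v_s^2)
# with theta the half-angle subtended by the disc chord at the detector.
disc_as_printed <- function(tt, v_s, D0, R0) {
  r <- v_s * tt
  out <- numeric(length(r))
  ok <- r > (D0 - R0) & r < (D0 + R0)
  cosang <- (D0^2 + r[ok]^2 - R0^2) / (2 * D0 * r[ok])
  out[ok] <- 2 * acos(pmin(pmax(cosang, -1), 1))
  out * v_s / (4 * pi * v_s^2)
}

# Two line charges +/-q at (-s,0)/(+s,0) inside a grounded circle of radius
# Rb (image charges), scaled so the potential at distance a_eff from the
# positive charge equals v_half.  Fully analytic oracle for the
# finite-difference potential solve with point electrodes.
two_line_charge_potential <- function(X, Y, s, Rb, a_eff, v_half) {
  G <- function(px_, py_, xx, yy) {
    rho <- sqrt(px_^2 + py_^2)
    pst <- c(px_, py_) * Rb^2 / rho^2
    -(1 / (2 * pi)) * (0.5 * log((xx - px_)^2 + (yy - py_)^2) -
                       0.5 * log((xx - pst[1])^2 + (yy - pst[2])^2) -
                       log(Rb / rho))
  }
  base <- G(-s, 0, X, Y) - G(s, 0, X, Y)
  th <- seq(0, 2 * pi, length.out = 361)[-1]
  bval <- mean(G(-s, 0, -s + a_eff * cos(th), a_eff * sin(th)) -
               G(s, 0, -s + a_eff * cos(th), a_eff * sin(th)))
  v_half / bval * base
}

# Effective electrostatic radius of a single grid node under the 5-point
# Laplacian (square-lattice Green's function constant).
lattice_point_radius <- function(pixel_size) {
  pixel_size * exp(-0.57721566490153286) / 2^1.5
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
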