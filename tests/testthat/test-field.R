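# Electric field solve, Joule dose and initial pressure.

test_that("zero applied voltage gives identically zero potential and field", {
  med <- muscle_medium(c(41, 41), 0.5e-3)
  ep <- electrode_pair(rbind(c(-2e-3, 0), c(2e-3, 0)), 0.6e-3,
                       mode = "1p1g", voltage = 0)
  phi <- solve_potential(med, ep)
  expect_equal(max(abs(phi)), 0)
  ef <- e_field(phi, med$pixel_size)
  expect_equal(max(ef$mag), 0)
})

test_that("potential equals applied values on electrodes and satisfies the
           discrete conservation law", {
  med <- muscle_medium(c(81, 81), 0.5e-3)
  ep <- electrode_pair(rbind(c(-3e-3, 0), c(3e-3, 0)), 0.75e-3,
                       mode = "1p1g", voltage = 500)
  phi <- solve_potential(med, ep)
  expect_equal(max(phi), 500)
  expect_true(min(phi) >= 0) # maximum principle: between boundary values
  # interior residual of div(sigma grad phi): 5-point stencil away from
  # electrodes and boundary must vanish (homogeneous sigma -> Laplacian)
  n <- 81
  lap <- phi[2:(n - 1), 2:(n - 1)] * -4 +
    phi[1:(n - 2), 2:(n - 1)] + phi[3:n, 2:(n - 1)] +
    phi[2:(n - 1), 1:(n - 2)] + phi[2:(n - 1), 3:n]
  x <- grid_coords(n, med$pixel_size)
  X <- matrix(x, n, n)[2:(n - 1), 2:(n - 1)]
  Y <- matrix(x, n, n, byrow = TRUE)[2:(n - 1), 2:(n - 1)]
  away <- sqrt((X - 3e-3)^2 + Y^2) > 1.5e-3 & sqrt((X + 3e-3)^2 + Y^2) > 1.5e-3
  expect_lt(max(abs(lap[away])) / 500, 1e-8)
})

test_that("finite-difference potential matches the two-line-charge analytic
           solution within 1% on the interior", {
  n <- 321
  px <- 0.25e-3
  med <- muscle_medium(c(n, n), px)
  D <- 8e-3
  V <- 100
  x <- grid_coords(n, px)
  ixp <- which.min(abs(x - D / 2))
  ixm <- which.min(abs(x + D / 2))
  # point-like electrodes (single pixel) at +/- V/2
  ep <- electrode_pair(rbind(c(x[ixm], 0), c(x[ixp], 0)), 0.45 * px,
                       voltage = V, voltages = c(V / 2, -V / 2))
  phi <- solve_potential(med, ep, boundary = "circle")
  Rb <- (n * px) / 2 - px / 2
  X <- matrix(x, n, n)
  Y <- matrix(x, n, n, byrow = TRUE)
  phi_an <- two_line_charge_potential(X, Y, s = D / 2, Rb = Rb,
                                      a_eff = lattice_point_radius(px),
                                      v_half = V / 2)
  r1 <- sqrt((X - D / 2)^2 + Y^2)
  r2 <- sqrt((X + D / 2)^2 + Y^2)
  rr <- sqrt(X^2 + Y^2)
  sub <- r1 > 2e-3 & r2 > 2e-3 & rr < 0.6 * Rb
  expect_lt(rel_l2(phi[sub], phi_an[sub]), 0.01)
})

test_that("2p drive gives a mirror-symmetric potential and dose map", {
  n <- 101
  med <- muscle_medium(c(n, n), 0.4e-3)
  ep <- electrode_pair(rbind(c(-4e-3, 0), c(4e-3, 0)), 0.8e-3,
                       mode = "2p", voltage = 800)
  fsol <- field_solution(med, ep, pulse_waveform(800))
  expect_lt(max(abs(fsol$potential - fsol$potential[n:1, ])) / 800, 1e-10)
  expect_lt(max(abs(fsol$dose - fsol$dose[n:1, ])) / max(fsol$dose), 1e-9)
})

test_that("1p1g field energy concentrates near the driven electrode", {
  n <- 129
  med <- muscle_medium(c(n, n), 0.25e-3)
  ep <- electrode_pair(rbind(c(-3e-3, 0), c(3e-3, 0)), 0.5e-3,
                       mode = "1p1g", voltage = 1000)
  fsol <- field_solution(med, ep, pulse_waveform(1000))
  x <- grid_coords(n, med$pixel_size)
  X <- matrix(x, n, n)
  Y <- matrix(x, n, n, byrow = TRUE)
  near <- function(cx) sum(fsol$dose[(X - cx)^2 + Y^2 <= (2e-3)^2])
  expect_gt(near(-3e-3), 2 * near(3e-3))
})

test_that("nominal field strength reproduces the plate-approximation labels", {
  expect_equal(nominal_field_strength(1200, 5e-3, "kV_per_cm"), 2.4)
  expect_equal(nominal_field_strength(1000, 1e-3, "kV_per_cm"), 10)
  expect_equal(nominal_field_strength(0, 3e-3), 0)
  expect_error(nominal_field_strength(100, 0), "gap")
})

test_that("energy deposition implements sigma E^2 tau with quadratic scaling", {
  med <- medium(c(11, 11), 1e-3, sigma = 1)
  e_mag <- matrix(1e5, 11, 11)
  H <- energy_deposition(e_mag, med, tau = 100e-9)
  # hand evaluation: 1 * (1e5)^2 * 1e-7 = 1e3 J/m^3
  expect_equal(max(abs(H - 1e3)), 0)
  # sigma = 0 -> no Joule heating
  med0 <- medium(c(11, 11), 1e-3, sigma = 0)
  expect_equal(max(abs(energy_deposition(e_mag, med0, tau = 100e-9))), 0)
  # doubling the voltage doubles E and quadruples H everywhere
  H4 <- energy_deposition(2 * e_mag, med, tau = 100e-9)
  expect_equal(H4, 4 * H)
})

test_that("initial pressure applies the local Grueneisen-like factor", {
  med <- medium(c(21, 21), 1e-3)
  H <- matrix(0, 21, 21)
  expect_equal(max(abs(initial_pressure(H, med))), 0)
  H[8:14, 8:14] <- 2e3
  p0 <- initial_pressure(H, med)
  gamma <- med$beta[1, 1] / (med$kappa[1, 1] * med$rho[1, 1] * med$c_v[1, 1])
  expect_equal(p0, gamma * H)
  # halving beta in one region halves p0 there only
  beta2 <- med$beta
  beta2[1:10, ] <- beta2[1:10, ] / 2
  med2 <- medium(c(21, 21), 1e-3, beta = beta2)
  p2 <- initial_pressure(H, med2)
  expect_equal(p2[1:10, ], p0[1:10, ] / 2)
  expect_equal(p2[11:21, ], p0[11:21, ])
})

test_that("degenerate or invalid electrode inputs are rejected", {
  med <- muscle_medium(c(41, 41), 0.5e-3)
  expect_error(electrode_pair(rbind(c(0, 0), c(1e-3, 0)), 0.6e-3),
               "overlap")
  ep_out <- electrode_pair(rbind(c(-10e-3, 0), c(10e-3, 0)), 0.8e-3,
                           mode = "1p1g", voltage = 10)
  expect_error(solve_potential(med, ep_out), "outside the domain")
  expect_error(medium(c(11, 11), 1e-3, sigma = -1), "sigma")
  expect_error(medium(c(11, 11), 1e-3, rho = 0), "rho")
})

test_that("max p0 follows a quadratic law in voltage (R^2 > 0.999)", {
  med <- muscle_medium(c(81, 81), 0.4e-3)
  volts <- seq(100, 1000, by = 100)
  peaks <- vapply(volts, function(v) {
    ep <- electrode_pair(rbind(c(-3e-3, 0), c(3e-3, 0)), 0.6e-3,
                         mode = "1p1g", voltage = v)
    max(field_solution(med, ep, pulse_waveform(v))$p0)
  }, numeric(1))
  fit <- lm(peaks ~ I(volts^2))
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)
})
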