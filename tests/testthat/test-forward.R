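# Green's-function forward model, band response and noise.

test_that("zero source propagates to identically zero traces", {
  geo <- ring_array(n_elements = 4, n_samples = 512)
  cd <- propagate(matrix(0, 21, 21), NULL, geo, pixel_size = 1e-4, v_s = 1497)
  expect_equal(max(abs(cd$traces)), 0)
})

test_that("a point source at the ring centre arrives at d/v_s on every
           element with identical traces", {
  geo <- ring_array(n_elements = 16, ring_radius = 0.05, sampling_rate = 40e6,
                    n_samples = 2048)
  p0 <- matrix(0, 41, 41)
  p0[21, 21] <- 1
  cd <- propagate(p0, NULL, geo, pixel_size = 1e-4, v_s = 1497)
  # symmetry: all 16 traces identical
  expect_equal(max(abs(sweep(cd$traces, 2, cd$traces[1, ]))), 0)
  tof <- estimate_tof(cd$traces[1, ], 40e6)
  expect_equal(tof, 0.05 / 1497, tolerance = 1 / 40e6 / (0.05 / 1497))
  # amplitude decays as 1/d: compare peak against a source off-centre
  cd2 <- propagate(p0, NULL, geo, pixel_size = 1e-4, v_s = 1497,
                   origin = c(25e-3, 0))
  d2 <- 0.05 - 25e-3
  expect_equal(max(abs(cd2$traces[1, ])) / max(abs(cd$traces[1, ])),
               0.05 / d2, tolerance = 0.02)
})

test_that("propagation is linear in the source map", {
  geo <- ring_array(n_elements = 3, n_samples = 1024)
  set.seed(42)
  a <- matrix(runif(41 * 41), 41, 41)
  b <- matrix(runif(41 * 41), 41, 41)
  pr <- function(m) propagate(m, NULL, geo, pixel_size = 2e-4, v_s = 1497)$traces
  expect_equal(pr(2 * a + 3 * b), 2 * pr(a) + 3 * pr(b), tolerance = 1e-12)
})

test_that("swapping source and detector leaves the arrival time unchanged", {
  fs <- 40e6
  p0 <- matrix(0, 11, 11)
  p0[6, 6] <- 1
  geo_a <- ring_array(n_elements = 1, ring_radius = 40e-3, sampling_rate = fs,
                      n_samples = 2048)
  # source at origin, detector at (40, 0) mm
  cd_a <- propagate(p0, NULL, geo_a, pixel_size = 1e-4, v_s = 1497)
  # source at (40, 0) mm is outside a 40 mm ring; use the mirrored layout:
  # detector ring rotated so its element sits at the origin-side position
  geo_b <- ring_array(n_elements = 1, ring_radius = 40e-3, sampling_rate = fs,
                      n_samples = 2048, element_angles = pi)
  cd_b <- propagate(p0, NULL, geo_b, pixel_size = 1e-4, v_s = 1497,
                    origin = c(0.1e-3, 0)) # sub-pixel shift, same distance set
  t_a <- estimate_tof(cd_a$traces[1, ], fs)
  t_b <- estimate_tof(cd_b$traces[1, ], fs)
  expect_equal(t_a, t_b, tolerance = 2 / fs / t_a)
})

test_that("derivative forward form matches the analytic uniform-disc
           solution away from the tangency singularities", {
  v_s <- 1497
  fs <- 40e6
  R0 <- 2e-3
  D0 <- 0.05
  pxd <- 1.25e-5
  nd <- 2 * ceiling(R0 / pxd) + 21
  xs <- grid_coords(nd, pxd)
  disc <- cover_disc(xs, pxd, R0)
  geo <- ring_array(n_elements = 1, ring_radius = D0, sampling_rate = fs,
                    n_samples = 2048)
  tt <- (seq_len(2048) - 1) / fs
  p_an <- disc_as_printed(tt, v_s, D0, R0)
  pd_an <- eatlab:::time_derivative(p_an, 1 / fs)

  cdp <- propagate(disc, NULL, geo, pixel_size = pxd, v_s = v_s,
                   form = "as_printed")
  expect_lt(rel_l2(cdp$traces[1, ], p_an), 0.02)

  cdd <- propagate(disc, NULL, geo, pixel_size = pxd, v_s = v_s,
                   form = "derivative")
  edges <- c((D0 - R0) / v_s, (D0 + R0) / v_s)
  keep <- abs(tt - edges[1]) > 4 / fs & abs(tt - edges[2]) > 4 / fs
  expect_lt(rel_l2(cdd$traces[1, keep], pd_an[keep]), 0.02)
  # bipolar N shape: positive lobe before the centre, negative after,
  # zero crossing at the arrival time of the disc centre within 2%
  i_max <- which.max(cdd$traces[1, ])
  i_min <- which.min(cdd$traces[1, ])
  expect_lt(i_max, i_min)
  zc <- i_max + which(cdd$traces[1, i_max:i_min] <= 0)[1] - 1
  expect_equal(tt[zc], D0 / v_s, tolerance = 0.02)
})

test_that("sources outside the ring or heterogeneous sound speed are
           rejected", {
  geo <- ring_array(n_elements = 4, ring_radius = 10e-3, n_samples = 512)
  p0 <- matrix(1, 11, 11)
  expect_error(
    propagate(p0, NULL, geo, pixel_size = 1e-4, v_s = 1497,
              origin = c(15e-3, 0)),
    "outside the detector ring"
  )
  vmap <- matrix(1497, 21, 21)
  vmap[1, 1] <- 1600
  med <- medium(c(21, 21), 1e-4, v_s = vmap)
  expect_error(propagate(matrix(1, 21, 21), med, geo), "uniform sound speed")
})

test_that("transducer response keeps in-band tones, kills DC and
           out-of-band energy, and preserves timing", {
  fs <- 40e6
  n <- 4096
  t <- (seq_len(n) - 1) / fs
  geo <- ring_array(n_elements = 1, sampling_rate = fs, n_samples = n)
  mk <- function(x) channel_data(matrix(x, 1), fs, geo)
  resp <- transducer_response()

  tone <- sin(2 * pi * 4e6 * t)
  out <- apply_response(mk(tone), resp)$traces[1, ]
  expect_equal(max(abs(out[500:3500])), 1, tolerance = 0.10) # within ~1 dB

  dc <- apply_response(mk(rep(1, n)), resp)$traces[1, ]
  expect_lt(max(abs(dc)), 1e-10)

  hi <- sin(2 * pi * 12e6 * t)
  out_hi <- apply_response(mk(hi), resp)$traces[1, ]
  expect_lt(max(abs(out_hi[500:3500])), 10^(-40 / 20)) # >= 40 dB down

  # zero phase: a band-limited pulse keeps its envelope-peak time
  nw <- make_nwave(n, fs, 40e-6, 4e6)
  t_in <- estimate_tof(nw, fs)
  t_out <- estimate_tof(apply_response(mk(nw), resp)$traces[1, ], fs)
  expect_equal(t_in, t_out, tolerance = 2 / fs / t_in)

  # broadband N-wave: filtered spectrum peaks inside 2-6 MHz
  nb <- make_nwave(n, fs, 40e-6, 8e6)
  fo <- apply_response(mk(nb), resp)$traces[1, ]
  sp <- Mod(fft(fo))[seq_len(n / 2)]
  f_peak <- (which.max(sp) - 1) / n * fs
  expect_gt(f_peak, 2e6)
  expect_lt(f_peak, 6e6)

  bad <- transducer_response(center_frequency = 15e6, band = c(10e6, 21e6))
  expect_error(apply_response(mk(tone), bad), "Nyquist")
})

test_that("seeded noise hits the requested SNR, is reproducible, and
           leaves the input untouched at snr = Inf", {
  fs <- 40e6
  n <- 4096
  geo <- ring_array(n_elements = 2, sampling_rate = fs, n_samples = n)
  clean <- rbind(make_nwave(n, fs, 40e-6), make_nwave(n, fs, 50e-6))
  cd <- channel_data(clean, fs, geo)

  n1 <- add_noise(cd, 20, seed = 123)
  n2 <- add_noise(cd, 20, seed = 123)
  expect_identical(n1$traces, n2$traces)
  n3 <- add_noise(cd, 20, seed = 124)
  expect_false(identical(n1$traces, n3$traces))

  measured <- 20 * log10(max(abs(clean)) / sd(n1$traces - clean))
  expect_equal(measured, 20, tolerance = 1 / 20)

  expect_identical(add_noise(cd, Inf, seed = 1)$traces, clean)
  cd0 <- channel_data(matrix(0, 2, n), fs, geo)
  expect_error(add_noise(cd0, 20, seed = 1), "all-zero")
})

test_that("end-to-end detected amplitude follows V^2 with R^2 > 0.999", {
  sw <- run_voltage_sweep(experiment_config("voltage_sweep", seed = 1,
    overrides = list(voltages = seq(200, 1000, by = 200), n = 65L,
                     pixel_size = 0.5e-3)))
  expect_equal(sw$exponent, 2, tolerance = 0.05 / 2)
  expect_gt(sw$power_r_squared, 0.999)
  expect_gt(sw$energy_r_squared, 0.999)
})
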