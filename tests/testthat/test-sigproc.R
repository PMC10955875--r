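# Trace processing: filters, wavelet denoising, SNR, envelope, TOF,
# sound-speed regression, frame averaging.

fs <- 40e6

test_that("low-pass filter passes a 1 MHz tone, rejects 12 MHz by 40 dB,
           and maps zero to zero", {
  n <- 4096
  t <- (seq_len(n) - 1) / fs
  lo <- lowpass(sin(2 * pi * 1e6 * t), 6e6, fs)
  expect_equal(max(abs(lo[500:3500])), 1, tolerance = 0.10)
  hi <- lowpass(sin(2 * pi * 12e6 * t), 6e6, fs)
  expect_lt(max(abs(hi[500:3500])), 10^(-40 / 20))
  expect_equal(lowpass(numeric(n), 6e6, fs), numeric(n))
  expect_error(lowpass(sin(t), 25e6, fs), "Nyquist")
})

test_that("periodized Coiflet DWT reconstructs perfectly at every order", {
  set.seed(7)
  x <- rnorm(512)
  for (ord in 1:3) {
    for (lv in c(1, 3, 5)) {
      expect_equal(idwt(dwt(x, lv, ord)), x, tolerance = 1e-12)
    }
  }
  expect_error(dwt(x, 0), "levels")
  expect_error(dwt(x[1:510], 5), "divisible")
})

test_that("wavelet denoising lifts a 20 dB N-wave to >= 35 dB and is
           near-lossless on clean input", {
  n <- 4096
  clean <- make_nwave(n, fs, 30e-6, 4e6)
  noisy <- clean + eatlab:::with_local_seed(99, rnorm(n, sd = 0.1)) # 20 dB
  den <- wavelet_denoise(noisy, denoise_spec())
  snr_out <- 20 * log10(max(abs(clean)) / sd(den - clean))
  expect_gte(snr_out, 35)
  # noise-free round trip: distortion below 1% relative L2
  expect_lt(rel_l2(wavelet_denoise(clean, denoise_spec()), clean), 0.01)
  expect_equal(wavelet_denoise(numeric(256), denoise_spec()), numeric(256))
  # non-dyadic lengths are padded transparently
  odd_len <- clean[seq_len(4000)]
  expect_length(wavelet_denoise(odd_len, denoise_spec()), 4000)
  expect_error(wavelet_denoise(c(clean[-1], NaN)), "non-finite")
})

test_that("SNR follows the peak-over-noise-sd definition", {
  trace <- c(rep(0.001, 500), 10, rep(0.001, 499))
  set.seed(3)
  noise_part <- rnorm(500, sd = 1)
  tr <- c(noise_part, trace)
  sig_win <- 501:1500
  noise_win <- 1:500
  measured <- compute_snr(tr, sig_win, noise_win)
  expect_equal(measured, 20 * log10(10 / sd(noise_part)), tolerance = 1e-12)
  # peak equal to noise sd -> 0 dB; ratio 10 -> 20 dB
  expect_equal(compute_snr(c(1, 0, 1), 1, 2:3) -
                 20 * log10(1 / sd(c(0, 1))), 0)
  expect_error(compute_snr(tr, 1:10, 5:20), "disjoint")
  expect_error(compute_snr(rep(1, 100), 1:50, 51:100), "zero standard deviation")
})

test_that("a 28.5 dB fixture is recovered within 1 dB", {
  n <- 8192
  clean <- 5 * make_nwave(n, fs, 120e-6, 4e6)
  sd_n <- 5 / 10^(28.5 / 20)
  tr <- clean + eatlab:::with_local_seed(17, rnorm(n, sd = sd_n))
  sig_win <- 4000:6000
  noise_win <- 1:2000
  expect_equal(compute_snr(tr, sig_win, noise_win), 28.5, tolerance = 1 / 28.5)
})

test_that("envelope is the analytic-signal magnitude", {
  n <- 2048
  t <- (seq_len(n) - 1) / fs
  tone <- 0.7 * sin(2 * pi * 5e6 * t)
  env <- envelope(tone)
  expect_equal(mean(env[100:1900]), 0.7, tolerance = 0.01)
  expect_equal(envelope(numeric(128)), numeric(128))
  nw <- make_nwave(n, fs, 25e-6, 4e6)
  env_nw <- envelope(nw)
  expect_gte(min(env_nw - abs(nw)), -1e-9) # never below the trace modulus
  # unimodal around the bipolar transition
  pk <- which.max(env_nw)
  expect_equal((pk - 1) / fs, 25e-6, tolerance = 0.01)
})

test_that("time-of-flight picking is shift-equivariant and signals no
           arrival on silence", {
  n <- 4096
  nw <- make_nwave(n, fs, 40e-6, 4e6)
  t1 <- estimate_tof(nw, fs)
  k <- 160
  shifted <- c(numeric(k), nw)[seq_len(n)]
  t2 <- estimate_tof(shifted, fs)
  expect_equal(t2 - t1, k / fs, tolerance = 1e-9 / (k / fs))
  expect_true(is.na(estimate_tof(numeric(n), fs)))
  # threshold picker returns an earlier time than the envelope peak
  t3 <- estimate_tof(nw, fs, method = "threshold", threshold_frac = 0.3)
  expect_lt(t3, t1)
})

test_that("sound-speed regression recovers slope and instrumental delay", {
  # exactly proportional data
  d <- c(0.02, 0.03, 0.04, 0.05)
  fit <- fit_sound_speed(d, d / 1500)
  expect_equal(fit$speed, 1500)
  expect_equal(fit$intercept_time, 0, tolerance = 1e-9)
  # unit rescaling (mm and us) rescales the slope by the same factor
  fit_mm_us <- fit_sound_speed(d * 1e3, d / 1500 * 1e6)
  expect_equal(fit_mm_us$speed, 1500 * 1e-3, tolerance = 1e-9)
  # delay shows up only in the intercept
  fit_d <- fit_sound_speed(d, d / 1500 + 2e-6)
  expect_equal(fit_d$speed, 1500)
  expect_equal(fit_d$intercept_time, 2e-6)
  expect_error(fit_sound_speed(d, rep(1e-5, 4)), "degenerate")
  expect_error(fit_sound_speed(0.03, 2e-5), "2 points")
})

test_that("frame averaging reduces white noise by sqrt(k) and tracks frame
           arithmetic", {
  set.seed(21)
  st <- frame_stack(array(rnorm(3000 * 2 * 16), c(3000, 2, 16)), 1e-3)
  av <- frame_average(st, 10)
  expect_equal(dim(av$frames)[1], 300)
  expect_equal(av$frame_interval, 10e-3)
  expect_equal(sd(av$frames) * sqrt(10), 1, tolerance = 0.10)
  # k = 1 is the identity
  expect_identical(frame_average(st, 1), st)
  # linearity
  st2 <- frame_stack(2 * st$frames, 1e-3)
  expect_equal(frame_average(st2, 10)$frames, 2 * av$frames)
  # non-divisible counts truncate with a warning
  st3 <- frame_stack(array(0, c(25, 2, 4)), 1e-3)
  expect_warning(av3 <- frame_average(st3, 10), "trailing")
  expect_equal(dim(av3$frames)[1], 2)
  expect_error(frame_average(st, 0), "k must be")
})

test_that("averaging then measuring SNR gains about 10 log10(k) dB", {
  n_frames <- 200
  k <- 10
  clean <- make_nwave(512, fs, 6e-6, 4e6)
  arr <- array(0, c(n_frames, 1, 512))
  set.seed(5)
  for (f in seq_len(n_frames)) arr[f, 1, ] <- clean + rnorm(512, sd = 0.1)
  st <- frame_stack(arr, 1e-3)
  av <- frame_average(st, k)
  snr_raw <- 20 * log10(1 / sd(arr[1, 1, ] - clean))
  snr_avg <- mean(vapply(seq_len(dim(av$frames)[1]), function(b) {
    20 * log10(1 / sd(av$frames[b, 1, ] - clean))
  }, numeric(1)))
  expect_gte(snr_avg - snr_raw, 10 * log10(k) - 1)
})
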