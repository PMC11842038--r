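test_that("baseline correction removes per-epoch means exactly", {
  ep <- epoch_set(rbind(rep(3, 100), sin(2 * pi * (0:99) / 10) + 3), fs = 100)
  out <- preprocess_epochs(ep)
  expect_equal(out$data[1, ], rep(0, 100))
  expect_equal(out$data[2, ], sin(2 * pi * (0:99) / 10) -
                 mean(sin(2 * pi * (0:99) / 10)), tolerance = 1e-12)
  zm <- epoch_set(matrix(rnorm(200), 2), fs = 100)
  zm$data <- zm$data - rowMeans(zm$data)
  expect_equal(preprocess_epochs(zm)$data, zm$data, tolerance = 1e-14)
  bad <- epoch_set(matrix(1, 2, 10), fs = 10)
  bad$data[1, 1] <- Inf
  expect_error(preprocess_epochs(bad), "non-finite")
})

test_that("noise floor is the mean of the flanking bins", {
  flat <- rep(2.5, 101)
  expect_equal(estimate_noise_floor(flat, c(20, 40), flank = 5), c(2.5, 2.5))
  spike <- rep(0, 101); spike[30] <- 7
  expect_equal(estimate_noise_floor(spike, 30, flank = 5), 0)
  ramp <- seq(0, 10, length.out = 101)
  expect_equal(estimate_noise_floor(ramp, 51, flank = 5), ramp[51],
               tolerance = 1e-12)
  expect_error(estimate_noise_floor(flat, 3, flank = 5), "edge")
})

test_that("reconstruction matches the dense-grid extremum oracle", {
  # single component: half peak-to-peak equals its amplitude
  w1 <- reconstruct_waveform(c(0.2, 0, 0, 0, 0), rep(0, 5), 120, 16384, 0.5)
  expect_equal((max(w1) - min(w1)) / 2, 0.2, tolerance = 1e-4)
  expect_equal(reconstruct_waveform(rep(0, 5), rep(0, 5), 120, 16384, 0.5),
               rep(0, 8192))
  set.seed(42)
  for (i in 1:10) {
    ptn <- runif(5) * c(0.1, 0.05, 0.02, 0.01, 0.005)
    ph <- runif(5, -pi, pi)
    w <- reconstruct_waveform(ptn, ph, 120, 16384, 0.5)
    expect_equal((max(w) - min(w)) / 2, oracle_half_pp(ptn, ph),
                 tolerance = 0.02)
  }
})

test_that("bootstrap spectrum recovers amplitude and phase at exact bins", {
  A <- 0.37; ph <- 0.9
  tr <- efr_ground_truth(amplitudes = c(A, 0, 0, 0, 0),
                         phases = c(ph, 0, 0, 0, 0))
  ep <- noiseless_epochs(tr, n_epochs = 12)
  sp <- draw_bootstrap_spectrum(ep, n_draws = 12, seed = 3)
  b <- sp$harmonic_bins[1]
  expect_equal(sp$freq[b], 120)
  expect_equal(sp$magnitude[b], A, tolerance = 1e-3)
  # single-bin DFT oracle on the windowed analytic sinusoid
  n <- 8192; t <- (0:(n - 1)) / 16384
  w <- tukey_window(n, 0.02)
  oracle_bin <- sum(w * A * cos(2 * pi * 120 * t + ph) *
                      exp(-2i * pi * (b - 1) * (0:(n - 1)) / n))
  expect_equal(sp$phase[b], Arg(oracle_bin), tolerance = 1e-9)
  expect_equal(sp$magnitude[b], 2 * Mod(oracle_bin) / sum(w), tolerance = 1e-9)
  # noise floor around a clean harmonic is tiny relative to the peak
  expect_lt(sp$noise_floor[1], 0.02 * A)
  expect_error(draw_bootstrap_spectrum(ep, n_draws = 11), "even")
})

test_that("noiseless EFR recovery is exact up to window leakage", {
  tr1 <- efr_ground_truth(amplitudes = c(0.1, 0, 0, 0, 0))
  ep1 <- noiseless_epochs(tr1)
  f1 <- efr_fit(ep1, n_draws = 8, n_boot = 3, seed = 1)
  expect_equal(f1$amplitude, 0.1, tolerance = 0.02)
  expect_equal(f1$bootstrap_sd, 0, tolerance = 1e-12)

  tr5 <- efr_ground_truth(phases = c(0.3, -1, 2, 0.5, -0.7))
  ep5 <- noiseless_epochs(tr5)
  f5 <- efr_fit(ep5, n_draws = 8, n_boot = 3, seed = 1)
  expect_equal(f5$amplitude,
               oracle_half_pp(tr5$amplitudes, tr5$phases), tolerance = 0.02)
  # invariance to bootstrap settings when all draws are identical
  f5b <- efr_fit(ep5, n_draws = 20, n_boot = 11, seed = 99)
  expect_equal(f5$amplitude, f5b$amplitude, tolerance = 1e-10)
})

test_that("EFR amplitude is linear in epoch scaling", {
  tr <- efr_ground_truth()
  ep <- generate_epochs(tr, noise_model(white_sd = 0.5, pink_sd = 0.5,
                                        gain_jitter = 0.05),
                        n_epochs = 60, n_samples = 2048, fs = 4096, seed = 5)
  f1 <- efr_fit(ep, n_draws = 60, n_boot = 20, seed = 7)
  ep3 <- ep; ep3$data <- ep$data * 3
  f3 <- efr_fit(ep3, n_draws = 60, n_boot = 20, seed = 7)
  expect_equal(f3$amplitude / f1$amplitude, 3, tolerance = 1e-6)
  expect_equal(f3$ptn / f1$ptn, rep(3, 5), tolerance = 1e-6)
})

test_that("EFR estimation is reproducible given the seed", {
  tr <- efr_ground_truth()
  ep <- generate_epochs(tr, noise_model(), n_epochs = 80,
                        n_samples = 2048, fs = 4096, seed = 2)
  a <- efr_fit(ep, n_draws = 80, n_boot = 15, seed = 10)
  b <- efr_fit(ep, n_draws = 80, n_boot = 15, seed = 10)
  expect_identical(a$amplitude, b$amplitude)
  expect_identical(a$boot_amplitudes, b$boot_amplitudes)
  c2 <- efr_fit(ep, n_draws = 80, n_boot = 15, seed = 11)
  expect_false(identical(a$amplitude, c2$amplitude))
  # different seeds stay within bootstrap variability of each other
  expect_lt(abs(a$amplitude - c2$amplitude),
            6 * max(a$bootstrap_sd, c2$bootstrap_sd) + 1e-3)
})

test_that("noise-floor subtraction reduces bias for near-floor components", {
  # a weak single envelope component near the spectral noise floor: without
  # the correction the floor-level harmonic magnitudes inflate the estimate
  tr <- efr_ground_truth(amplitudes = c(0.02, 0, 0, 0, 0))
  truth_amp <- 0.02
  err_corr <- err_raw <- numeric(60)
  for (i in 1:60) {
    ep <- generate_epochs(tr, noise_model(white_sd = 1, pink_sd = 0,
                                          gain_jitter = 0),
                          n_epochs = 50, n_samples = 2048, fs = 4096,
                          seed = 1000 + i)
    fc <- efr_fit(ep, n_draws = 50, n_boot = 25, seed = i)
    fr <- efr_fit(ep, n_draws = 50, n_boot = 25, nf_correct = FALSE, seed = i)
    err_corr[i] <- abs(fc$amplitude - truth_amp)
    err_raw[i] <- abs(fr$amplitude - truth_amp)
  }
  expect_lt(mean(err_corr), mean(err_raw))
  # and for pure noise the corrected estimate collapses toward zero
  tr0 <- efr_ground_truth(amplitudes = rep(0, 5))
  e0c <- e0r <- numeric(20)
  for (i in 1:20) {
    ep <- generate_epochs(tr0, noise_model(white_sd = 1, pink_sd = 0,
                                           gain_jitter = 0),
                          n_epochs = 100, n_samples = 2048, fs = 4096,
                          seed = 3000 + i)
    e0c[i] <- efr_fit(ep, n_draws = 100, n_boot = 25, seed = i)$amplitude
    e0r[i] <- efr_fit(ep, n_draws = 100, n_boot = 25,
                      nf_correct = FALSE, seed = i)$amplitude
  }
  expect_lt(mean(e0c), mean(e0r))
})

test_that("harmonic bins off the spectral grid trigger a warning", {
  tr <- efr_ground_truth(fm = 123)   # not a multiple of the 2-Hz resolution
  ep <- noiseless_epochs(tr)
  expect_warning(efr_fit(ep, fm = 123, n_draws = 8, n_boot = 2, seed = 1),
                 "off-bin")
})
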