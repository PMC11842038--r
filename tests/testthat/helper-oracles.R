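# Independent oracles used across test files.

# dense-grid extremum oracle for a 5-harmonic stack: half peak-to-peak of
# sum_k ptn_k cos(2 pi k fm t + phase_k), evaluated over one modulation
# period on a grid fine enough that the extremum error is negligible
oracle_half_pp <- function(ptn, phases, fm = 120, n_grid = 2e5) {
  t <- seq(0, 1 / fm, length.out = n_grid)
  w <- numeric(n_grid)
  for (k in seq_along(ptn)) w <- w + ptn[k] * cos(2 * pi * k * fm * t + phases[k])
  (max(w) - min(w)) / 2
}

# closed-form RMS of the analytic SAM waveform
sam_rms_closed_form <- function(md) sqrt((1 + md^2 / 2) / 2)

# closed-form RAM/SAM RMS ratio in dB after scaling RAM by `scale`
# (duty-cycle average of the squared envelope, halved for the carrier)
ram_sam_rms_db_closed_form <- function(md = 0.95, duty = 0.25, scale = 0.5) {
  ram_ms <- scale^2 * (duty * (2 + 2 * md)^2 + (1 - duty) * (2 - 2 * md)^2) / 2
  sam_ms <- (1 + md^2 / 2) / 2
  10 * log10(ram_ms / sam_ms)
}

# a noiseless, gain-stable epoch set for a given ground truth
noiseless_epochs <- function(truth, n_epochs = 8, fs = 16384,
                             n_samples = 8192, seed = 1) {
  generate_epochs(truth, noise_model(white_sd = 0, pink_sd = 0,
                                     gain_jitter = 0),
                  n_epochs = n_epochs, fs = fs, n_samples = n_samples,
                  seed = seed)
}

# evaluate raw cubic coefficients (c0..c3) at x
poly_eval_test <- function(cf, x) cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
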