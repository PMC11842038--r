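# Synthetic-data generators with known ground truth.
#
# These generators emulate the inputs of the measurement chain: multi-harmonic
# phase-locked responses buried in colored EEG noise with epoch-to-epoch
# variability, monotone DPOAE growth with additive measurement noise,
# psychometric listeners driving a 1-up/1-down adaptive speech test, and a
# three-group listener cohort with a targeted rank-correlation structure.
# Every generator is deterministic given its seed and stamps seed and
# parameters into its output.

#' Ground truth for a synthetic envelope-following response
#'
#' @param fm modulation frequency, Hz.
#' @param amplitudes harmonic amplitudes at k*fm for k = 1..5, uV.
#' @param phases harmonic phases, radians (cosine convention).
#' @return object of class `efr_ground_truth`.
#' @export
efr_ground_truth <- function(fm = 120,
                             amplitudes = c(0.1, 0.05, 0.02, 0.01, 0.005),
                             phases = rep(0, 5)) {
  stopifnot(length(amplitudes) == 5, length(phases) == 5,
            all(amplitudes >= 0))
  structure(list(fm = fm, amplitudes = amplitudes, phases = phases),
            class = "efr_ground_truth")
}

#' EEG-like noise model
#'
#' White plus 1/f^alpha Gaussian noise with an optional per-epoch
#' multiplicative gain jitter; a minimal model of the physiological EEG floor.
#'
#' @param white_sd white-noise SD, uV.
#' @param pink_sd 1/f-noise SD, uV.
#' @param pink_exponent spectral slope alpha of the 1/f^alpha component.
#' @param gain_jitter SD of the per-epoch multiplicative response gain.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 1, pink_sd = 1, pink_exponent = 1,
                        gain_jitter = 0.1) {
  stopifnot(white_sd >= 0, pink_sd >= 0, pink_exponent >= 0, gain_jitter >= 0)
  structure(list(white_sd = white_sd, pink_sd = pink_sd,
                 pink_exponent = pink_exponent, gain_jitter = gain_jitter),
            class = "noise_model")
}

# one epoch's worth of 1/f^alpha noise, unit SD, via spectral shaping
pink_noise <- function(n, alpha) {
  half <- floor(n / 2)
  f <- c(1, seq_len(half))             # DC bin excluded from shaping
  shape <- c(0, 1 / f[-1]^(alpha / 2))
  re <- stats::rnorm(half + 1) * shape
  im <- stats::rnorm(half + 1) * shape
  spec <- complex(real = re, imaginary = im)
  full <- c(spec, Conj(rev(spec[2:(n - half)])))
  x <- Re(stats::fft(full[seq_len(n)], inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x / s
}

#' Generate an epoch set with known harmonic ground truth
#'
#' Each epoch is `g_e * sum_k A_k cos(2*pi*k*fm*t + phase_k)` plus
#' independent white and 1/f^alpha noise, where `g_e` is a per-epoch
#' multiplicative gain. Polarity labels alternate; the envelope-locked
#' response itself is polarity-invariant, mirroring real recordings where
#' alternating the carrier polarity cancels stimulus artifact but preserves
#' envelope components.
#'
#' @param truth an [efr_ground_truth()].
#' @param noise a [noise_model()].
#' @param n_epochs number of epochs.
#' @param fs sampling rate, Hz (default 16384).
#' @param n_samples samples per epoch (default 8192, i.e. a 2-Hz bin
#'   resolution that places `fm = 120` exactly on a bin).
#' @param seed integer seed.
#' @return an [epoch_set()] with attributes `seed`, `truth` and `noise`.
#' @export
generate_epochs <- function(truth, noise = noise_model(), n_epochs = 1000,
                            fs = 16384, n_samples = 8192, seed = 1) {
  stopifnot(inherits(truth, "efr_ground_truth"),
            inherits(noise, "noise_model"))
  if (max(seq_along(truth$amplitudes)) * truth$fm >= fs / 2)
    stop("harmonics exceed the Nyquist frequency")
  set.seed(seed)
  t <- (seq_len(n_samples) - 1) / fs
  sig <- numeric(n_samples)
  for (k in seq_along(truth$amplitudes))
    sig <- sig + truth$amplitudes[k] *
      cos(2 * pi * k * truth$fm * t + truth$phases[k])
  data <- matrix(0, n_epochs, n_samples)
  gains <- 1 + stats::rnorm(n_epochs, sd = noise$gain_jitter)
  for (e in seq_len(n_epochs)) {
    eps <- numeric(n_samples)
    if (noise$white_sd > 0)
      eps <- eps + stats::rnorm(n_samples, sd = noise$white_sd)
    if (noise$pink_sd > 0)
      eps <- eps + noise$pink_sd * pink_noise(n_samples, noise$pink_exponent)
    data[e, ] <- gains[e] * sig + eps
  }
  out <- epoch_set(data, fs)
  attr(out, "seed") <- seed
  attr(out, "truth") <- truth
  attr(out, "noise") <- noise
  out
}

#' Generate a DPOAE growth function from a known monotone curve
#'
#' @param true_curve polynomial coefficients c0..c3 of the true
#'   `Ldc(L2)` curve (dB SPL), or a function of L2.
#' @param L2_levels strictly increasing primary levels, dB SPL
#'   (default 30-60 in 6-dB steps).
#' @param noise_sd Gaussian measurement noise SD added to each mean point, dB.
#' @param point_sd per-point SD recorded in the table (defaults to
#'   `noise_sd`).
#' @param seed integer seed.
#' @return a [dp_growth()] with attribute `seed`.
#' @export
generate_dp_growth <- function(true_curve, L2_levels = seq(30, 60, 6),
                               noise_sd = 1, point_sd = NULL, seed = 1) {
  if (length(L2_levels) < 4) stop("at least 4 levels are required")
  if (any(diff(L2_levels) <= 0)) stop("L2 levels must be strictly increasing")
  f <- if (is.function(true_curve)) true_curve
       else function(x) poly_eval(c(true_curve, rep(0, 4 - length(true_curve))), x)
  set.seed(seed)
  mu <- f(L2_levels) + stats::rnorm(length(L2_levels), sd = noise_sd)
  sd_rec <- point_sd %||% noise_sd
  out <- dp_growth(L2_levels, mu, rep(sd_rec, length(L2_levels)))
  attr(out, "seed") <- seed
  out
}

#' Psychometric listener model for the matrix sentence test
#'
#' Word-level probability correct
#' `p(L) = guess + (1 - guess) * logistic((L - srt50) * 4 * slope)`, so that
#' `slope` is the psychometric slope (proportion correct per dB) at the
#' midpoint and `srt50` the level of 50% correct for a zero guess rate.
#'
#' @param srt50 speech reception threshold, dB (SPL or SNR depending on
#'   condition).
#' @param slope psychometric slope at the midpoint, /dB (default 0.15,
#'   typical for matrix sentence tests).
#' @param guess_rate lapse-free guessing floor, in \[0, 0.5).
#' @return object of class `listener_model`.
#' @export
listener_model <- function(srt50, slope = 0.15, guess_rate = 0) {
  stopifnot(slope > 0, guess_rate >= 0, guess_rate < 0.5)
  structure(list(srt50 = srt50, slope = slope, guess_rate = guess_rate),
            class = "listener_model")
}

#' Probability of a correct word at a given level
#' @param listener a [listener_model()].
#' @param level presentation level, dB.
#' @return probability in \[0, 1\].
#' @export
word_prob <- function(listener, level) {
  p <- 1 / (1 + exp(-(level - listener$srt50) * 4 * listener$slope))
  listener$guess_rate + (1 - listener$guess_rate) * p
}

#' Simulate word scoring for one sentence
#'
#' Binomial draw of correct words out of `n_words` at the listener's
#' psychometric probability.
#'
#' @inheritParams word_prob
#' @param n_words words per sentence (default 5).
#' @param seed optional integer seed (omit inside a seeded caller).
#' @return integer count of correctly identified words.
#' @export
simulate_word_scores <- function(listener, level, n_words = 5, seed = NULL) {
  stopifnot(n_words >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(1, n_words, word_prob(listener, level))
}

#' Run a 1-up/1-down adaptive SRT track with word scoring
#'
#' After each 5-word sentence the level moves by
#' `-2 * step * (proportion correct - 0.5)` (down for better-than-half
#' scoring), with the step size decaying by `step_decay` at every reversal of
#' track direction. The SRT estimate is the mean presentation level over the
#' trailing `n_tail` sentences.
#'
#' @param listener a [listener_model()].
#' @param start_level initial speech level, dB (default 70).
#' @param n_sentences sentences per track (default 20); at least 5.
#' @param n_words words per sentence.
#' @param step_initial initial step size, dB.
#' @param step_decay multiplicative step decay per reversal.
#' @param n_tail trailing sentences averaged for the SRT.
#' @param seed integer seed.
#' @return list with `srt` (dB), `levels` (per-sentence presentation levels),
#'   `scores`, and the configuration.
#' @export
run_adaptive_track <- function(listener, start_level = 70, n_sentences = 20,
                               n_words = 5, step_initial = 5,
                               step_decay = 0.8, n_tail = 10, seed = 1) {
  stopifnot(inherits(listener, "listener_model"), n_sentences >= 5)
  set.seed(seed)
  level <- start_level
  step <- step_initial
  prev_dir <- 0
  levels <- scores <- numeric(n_sentences)
  for (s in seq_len(n_sentences)) {
    levels[s] <- level
    k <- stats::rbinom(1, n_words, word_prob(listener, level))
    scores[s] <- k
    delta <- -2 * step * (k / n_words - 0.5)
    d <- sign(delta)
    if (d != 0 && prev_dir != 0 && d != prev_dir) step <- step * step_decay
    if (d != 0) prev_dir <- d
    level <- level + delta
  }
  list(srt = mean(levels[(n_sentences - min(n_tail, n_sentences) + 1):n_sentences]),
       levels = levels, scores = scores,
       config = list(start_level = start_level, n_sentences = n_sentences,
                     n_words = n_words, step_initial = step_initial,
                     step_decay = step_decay, n_tail = n_tail, seed = seed))
}

#' Linear-phase FIR band splitting
#'
#' Designs an order-`order` linear-phase FIR filter (Hamming window design)
#' and applies it with group-delay compensation, as used to derive the
#' low-pass and high-pass speech material.
#'
#' @param x signal.
#' @param fs sampling rate, Hz.
#' @param mode `"lp"` or `"hp"`.
#' @param cutoff cutoff frequency, Hz (below Nyquist).
#' @param order filter order in taps (default 1024).
#' @return filtered signal, same length as `x`.
#' @export
fir_bandsplit <- function(x, fs, mode = c("lp", "hp"), cutoff, order = 1024) {
  mode <- match.arg(mode)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (order < 2) stop("order must be at least 2")
  h <- signal::fir1(order, cutoff / (fs / 2),
                    type = if (mode == "lp") "low" else "high")
  y <- stats::convolve(x, rev(h), type = "open")
  d <- floor(length(h) / 2)
  y[(d + 1):(d + length(x))]
}

## ---- cohort generation -----------------------------------------------------

cohort_vars <- c("age", "th_a", "th_dp", "efr_sam", "efr_ram",
                 "srt_siq_bb", "srt_siq_lp", "srt_siq_hp",
                 "srt_sin_bb", "srt_sin_lp", "srt_sin_hp")

cohort_groups <- c("yNH", "yNH_excluded", "oNH", "oHI")

# Within-group correlation structure from a 3-factor loading model:
# factor 1 = envelope-coding integrity (synaptopathy), factor 2 = hearing
# sensitivity (OHC integrity), factor 3 = general speech-test ability.
# The EFR_RAM x SRT_SiN-HP loading is solved so that the implied Gaussian
# copula gives a within-group Spearman correlation of exactly -0.73.
default_loadings <- function() {
  L <- rbind(
    age        = c( 0.00,  0.00, 0.00),
    th_a       = c(-0.10,  0.92, 0.00),
    th_dp      = c(-0.10,  0.88, 0.00),
    efr_sam    = c( 0.55, -0.05, 0.00),
    efr_ram    = c( 0.90, -0.10, 0.00),
    srt_siq_bb = c(-0.40,  0.45, 0.50),
    srt_siq_lp = c(-0.30,  0.30, 0.50),
    srt_siq_hp = c(-0.55,  0.55, 0.40),
    srt_sin_bb = c(-0.55,  0.30, 0.50),
    srt_sin_lp = c(-0.25,  0.20, 0.50),
    srt_sin_hp = c(NA,     0.30, 0.35))
  r_key <- 2 * sin(pi * (-0.73) / 6)   # Pearson equivalent of Spearman -0.73
  L["srt_sin_hp", 1] <-
    (r_key - L["efr_ram", 2] * L["srt_sin_hp", 2]) / L["efr_ram", 1]
  L
}

#' Cohort generator parameters
#'
#' Per-group sample sizes, means and SDs for every cohort variable, and the
#' within-group Spearman correlation target. Group means and SDs printed in
#' the source study (ages, 4-kHz audiometric thresholds, SAM/RAM EFR
#' amplitudes) are the defaults; quantities the study does not print per
#' group (SRT means/SDs, DPOAE thresholds) are plausible matrix-test
#' defaults and are configuration, not reference values.
#'
#' @param n named integer vector of group sizes.
#' @param means,sds numeric group-by-variable matrices (rows `yNH`,
#'   `yNH_excluded`, `oNH`, `oHI`).
#' @param spearman target within-group Spearman correlation matrix across the
#'   11 cohort variables; must be symmetric and, after conversion to the
#'   Gaussian-copula Pearson scale, positive semi-definite.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n = c(yNH = 13, yNH_excluded = 2, oNH = 15, oHI = 14),
                          means = NULL, sds = NULL, spearman = NULL) {
  if (is.null(means)) {
    means <- rbind(
      #           age  th_a th_dp efr_sam efr_ram siq_bb siq_lp siq_hp sin_bb sin_lp sin_hp
      yNH          = c(24.5,  3.3,  8.0, 0.065, 0.239, 18.5, 23.0, 30.0, -7.1, -4.8, -2.5),
      yNH_excluded = c(24.5,  5.0, 30.0, 0.065, 0.239, 18.5, 23.0, 30.0, -7.1, -4.8, -2.5),
      oNH          = c(64.2, 11.3, 18.0, 0.063, 0.155, 22.0, 27.0, 40.0, -5.6, -3.8,  0.5),
      oHI          = c(65.2, 36.0, 38.9, 0.059, 0.095, 32.0, 33.0, 52.0, -5.0, -3.5,  1.2))
    colnames(means) <- cohort_vars
  }
  if (is.null(sds)) {
    sds <- rbind(
      yNH          = c(2.2, 3.5,  7.0, 0.022, 0.076, 2.5, 2.5, 3.5, 1.0, 1.2, 1.5),
      yNH_excluded = c(2.2, 4.0,  3.0, 0.022, 0.076, 2.5, 2.5, 3.5, 1.0, 1.2, 1.5),
      oNH          = c(1.9, 3.5,  8.0, 0.031, 0.062, 3.0, 3.0, 5.0, 1.2, 1.4, 2.0),
      oHI          = c(1.7, 8.4, 10.0, 0.031, 0.028, 5.0, 4.5, 6.0, 1.4, 1.5, 2.0))
    colnames(sds) <- cohort_vars
  }
  if (is.null(spearman)) {
    L <- default_loadings()
    P <- L %*% t(L)
    diag(P) <- 1
    spearman <- (6 / pi) * asin(P / 2)
    diag(spearman) <- 1
  }
  if (!isTRUE(all.equal(spearman, t(spearman))))
    stop("spearman target must be symmetric")
  P <- 2 * sin(pi * spearman / 6)
  diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("spearman target is not positive semi-definite on the copula scale")
  stopifnot(all(rownames(means) == cohort_groups),
            all(rownames(sds) == cohort_groups),
            all(names(n) == cohort_groups), all(sds >= 0))
  structure(list(n = n, means = means, sds = sds, spearman = spearman,
                 pearson = P),
            class = "cohort_params")
}

#' Generate a synthetic listener cohort
#'
#' Per group, draws from a Gaussian copula with the target within-group
#' Spearman correlation matrix (converted to the Pearson scale via
#' `2*sin(pi*rho/6)`) and Gaussian margins at the group means/SDs. Group
#' labels are attached; seeded runs are reproducible.
#'
#' @param params a [cohort_params()].
#' @param n_per_group optional single integer overriding every group size
#'   (used for large-sample fidelity checks).
#' @param seed integer seed.
#' @return data.frame of class `cohort_table` with columns `subject`,
#'   `group`, and the 11 cohort variables; attributes `seed` and `params`.
#' @export
generate_cohort <- function(params = cohort_params(), n_per_group = NULL,
                            seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  R <- chol(params$pearson)
  n <- params$n
  if (!is.null(n_per_group)) n[] <- n_per_group
  p <- length(cohort_vars)
  rows <- vector("list", length(n))
  for (g in seq_along(n)) {
    Z <- matrix(stats::rnorm(n[g] * p), n[g], p) %*% R
    X <- sweep(sweep(Z, 2, params$sds[g, ], `*`), 2, params$means[g, ], `+`)
    colnames(X) <- cohort_vars
    rows[[g]] <- data.frame(group = names(n)[g], X)
  }
  out <- do.call(rbind, rows)
  out <- cbind(subject = sprintf("S%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "params") <- params
  out
}
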