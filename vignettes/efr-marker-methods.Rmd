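---
title: "Methods: envelope-following response markers, DPOAE thresholds, and the cohort battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope-following response markers, DPOAE thresholds, and the cohort battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramefr)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not emulate,
and the numerical decisions taken where the procedure left room.

## 1. Stimuli

Two amplitude-modulated pure tones share a carrier `f` (default 4 kHz, well
above the phase-locking limit, so the evoked response reflects envelope
coding) and a modulation frequency `f_m` (default 120 Hz):

* **SAM** — sinusoidal modulator: `x(t) = [1 + md·sin(2πf_m t + φ)]·sin(2πf t)`.
* **RAM** — rectangular modulator with duty cycle τ:
  `y(t) = [2 + 2md·m(t)]·sin(2πf t)`, `m(t) ∈ {+1, −1}`, high during the
  fraction τ of each modulation period.

Defaults: modulation depth `md = 0.95` (−0.45 dB re full modulation),
modulator phase `φ = 3π/2`, τ = 0.25, 0.4 s duration at 48 kHz, 2.5%
tapered-cosine onset/offset window. The rectangular modulator is evaluated
pointwise at sample times with no band-limiting — the modulator is ideal by
construction, and any spectral splatter above Nyquist is irrelevant at the
44-kHz-wide sampling used.

**Level matching.** The RAM stimulus is presented at the same *waveform
peak-to-peak amplitude* as the SAM reference, not the same RMS. With
`md = 0.95` the RAM envelope extremes are 3.9/0.1 against SAM's 1.95/0.05,
so the matching scale is 0.5 and the RMS offset is
`10·log10(0.25·(0.25·3.9² + 0.75·0.1²)/2 ÷ (1 + md²/2)/2) ≈ −1.83 dB`:
a 70 dB SPL SAM reference yields a matched RAM level of 68.17 → 68 dB SPL.
Peak-to-peak is evaluated on the rendered waveform before windowing; a 2.5%
taper affects the extremes negligibly, but the convention is fixed so the
matching is reproducible. dB SPL is referenced to 20 μPa RMS, and absolute
calibration is carried as a single linear scale on the stimulus object —
transducer chains are out of scope.

## 2. The EFR amplitude estimator

The estimator (`efr_fit()`) quantifies the scalp-recorded envelope-following
response from an epochs-by-samples matrix in μV with per-epoch polarity
labels. The chain, per bootstrap run *b* of `n_boot = 200`:

1. draw `n_draws = 1000` epochs with replacement, 500 per stimulus polarity
   (averaging across polarities cancels carrier-locked and stimulus-artifact
   components while envelope-locked components survive);
2. window each epoch with a 2% tapered-cosine window and average the complex
   DFT spectra;
3. normalize magnitudes to μV of sinusoid amplitude — one-sided spectrum,
   divided by the window's coherent gain `sum(w)` and doubled. With this
   convention an epoch containing `A·cos(2πkf_m t + θ)` produces magnitude
   `A` and phase `θ` at the harmonic bin exactly (up to window leakage);
4. estimate the noise floor `NF_k` at each harmonic `k·f_m`, `k = 1..5`, as
   the mean magnitude of the five bins on each side of the harmonic bin;
5. form peak-to-noise-floor magnitudes `PtN_k = max(0, |F_k| − NF_k)`;
6. reconstruct `W_b(t) = Σ_k PtN_k·cos(2πkf_m t + θ_k)` on the epoch grid
   using the original phases `θ_k`, all non-harmonic bins zero;
7. the per-run amplitude is `(max W_b − min W_b)/2`.

The reported EFR amplitude is half the peak-to-peak of the *average*
waveform `W̄ = mean_b(W_b)`; the bootstrap SD is the SD of the per-run
amplitudes. For noiseless input every draw is identical, so the estimate is
invariant to `n_boot` and `n_draws` and the SD is zero; the estimator is
also exactly linear in an overall scaling of the epochs, because noise-floor
subtraction is scale-equivariant.

**Numerical decisions.**

* *Negative PtN is clipped at zero before reconstruction.* A negative
  spectral amplitude has no physical meaning and would corrupt the
  reconstruction; the procedure description is silent on the point, so the
  clip is stated here and asserted in tests.
* *Harmonic bin location* is the nearest DFT bin to `k·f_m`. The synthetic
  defaults (16384 Hz, 8192-sample epochs → 2-Hz bins) put 120 Hz exactly on
  bin 61, avoiding scalloping; when a harmonic falls off-grid by more than
  10% of a bin the fit warns rather than silently mis-centering.
* *Windowed-leakage bias.* The 2% taper leaks a small fraction of each
  harmonic's energy into its flanking bins, so the noise floor under a
  strong clean component is not exactly zero and the corrected amplitude
  sits ~1–2% below truth. Tests therefore use a 2% tolerance for noiseless
  recovery, verified against a dense-grid extremum oracle evaluated at
  2×10⁵ points per modulation period.
* *When the correction helps.* Noise-floor subtraction is a conservative
  correction: for components far above the floor it overcorrects slightly
  (≈ the Rayleigh-mean floor), while for components at or below the floor it
  removes the large positive bias that raw magnitudes would contribute
  (a pure-noise epoch set yields ≈ 0.0002 μV corrected versus ≈ 0.014 μV
  raw under the test conditions). The property tests exercise exactly this
  regime, which is the regime the marker operates in for weak responses.
  Passing them shows the correction behaves as designed around the floor;
  it does not make the estimator unbiased for strong components.

## 3. DPOAE growth and thresholds

Distortion-component growth functions `L_DC(L2)` are measured at primary
levels `L2 = 30–60 dB SPL in 6-dB steps` with Scissors-rule primaries
(`L1 = 0.4·L2 + 39`) and a fixed `f2/f1 = 1.2`. The component level is
extracted with a least-squares-fit filter: amplitude of the best
`a·cos + b·sin` fit at the target frequency over consecutive windows of
width `1/bandwidth` (2 Hz default → 0.5-s windows), averaged and expressed
in dB SPL.

The threshold estimator (`dpoae_fit()`) bootstraps the growth function:
each draw resamples every point from a Gaussian with the recorded per-point
SD, truncated at ±1.96 SD — the most literal reading of "draws constrained
to each point's confidence interval". Monotone growth is enforced first by
endpoint elimination (only the outermost point of a decreasing adjacent
pair may be dropped, never an interior point; fewer than three survivors is
a failed draw), then a least-squares cubic is fitted and rejected unless
non-decreasing over the retained range (with exactly three points a
quadratic is fitted, since a cubic would be underdetermined). The cubic is
fitted in a centered variable and re-expanded to raw coefficients, which
keeps the normal equations well-conditioned over 30–60 dB ranges.

**Threshold root.** TH_DP is the L2 at which the fitted curve reaches the
−25 dB SPL criterion, extrapolation permitted down to 30 dB below the
lowest measured level. The root is located by *walking down from the top of
the fitted range* to the first crossing below the criterion, rather than
taking the globally smallest root in the extrapolation window: a cubic's
tail can re-cross the criterion far below the measured range, and those
spurious roots belong to the polynomial, not to the growth function. For a
curve monotone through the crossing both definitions coincide; for noisy
draws the walk-down rule removes a heavy left tail from the bootstrap
distribution. The reported TH_DP is the *median* over valid draws with its
SD; draws that never reach the criterion are counted and excluded, and an
estimate with zero valid draws is returned as an explicit no-threshold
result. Low outlying thresholds across a cohort can be replaced at the
Tukey fence `Q1 − 1.5·IQR` (`winsorize_low_thresholds()`), the reading
adopted for the ambiguous winsorization rule, to avoid high-leverage points
in regressions.

The "adapted cubic" of the original fitting literature is not reproduced in
the source description; a monotonicity-constrained ordinary cubic with
rejection sampling is the documented stand-in, matching the described
behavior (monotone fits, endpoint elimination, extrapolated criterion
crossing).

## 4. Cohort statistics

* `correlation_auto()` reports Pearson's *r* when both variables pass
  Shapiro–Wilk normality at α = 0.05 (the gate level is fixed here as a
  package choice), otherwise Spearman's ρ.
* `bonferroni_adjust()` implements `min(1, p·m)` with an explicit family
  size, since correction factors are often fixed per figure rather than per
  p-value vector.
* `pos_ttest()` implements the Derrick partially-overlapping-samples
  statistic in both the pooled-variance and Welch-type forms, with the
  published degrees-of-freedom interpolations. The Welch-type form nests
  the paired t-test exactly when all observations are paired; the pooled
  form nests the Student independent-samples test when none are. Both
  variants are provided because the variance assumption behind published
  mixed-design results cannot generally be recovered from counts alone.
  Monte-Carlo calibration over 10⁴ i.i.d.-normal null replicates of a
  3-paired/11-pre/4-post design keeps the type-I error within [0.04, 0.06]
  at nominal 0.05.
* `commonality()` decomposes the full-model R² over 2 or 3 predictors by
  solving the all-subsets system (the components touching any predictor
  set A must sum to R²(A)); components sum to the full R² to 1e-10 by
  construction of the solve.
* `fit_linear_models()` wraps `lm` with the diagnostics used for cohort
  regressions: VIF (on the additive model), Durbin–Watson, and residual
  normality. `residualize()` provides the hearing-threshold correction of
  SRTs; its output is exactly orthogonal to the covariate.
* `fit_piecewise_growth()` fits a continuous two-segment line with either a
  fixed or grid-scanned knee, for EFR growth-versus-level reanalyses where a
  compression knee near 60 dB SPL separates shallow supra-threshold growth
  (≈ 0.002 μV/dB) from steeper low-level growth. `db_to_microvolt()`
  supports reanalysis of amplitudes reported in dB re 1 μV.

## 5. Synthetic data: what it emulates, and what it does not

The generators provide ground truth for validating the estimators, not
physiological realism:

* **Epochs** are harmonic stacks in white + 1/f^α Gaussian noise (α = 1 by
  default — the minimal model that reproduces an EEG-like sloping floor for
  noise-floor-correction testing) with a per-epoch multiplicative gain
  jitter (SD 0.1) standing in for arousal and impedance drift. Defaults:
  16384 Hz, 8192-sample epochs, 1000 epochs alternating polarity. Real EEG
  additionally contains line noise, blinks/EMG artifacts, non-stationary
  floors and channel topography; none are modelled, so passing tests
  demonstrates estimator correctness, not robustness to artifacts.
* **Adaptive SRT tracks** score 5-word sentences from a logistic
  psychometric listener (slope 0.15/dB at midpoint by default, a typical
  matrix-test value) and move the level by `−2·step·(p_correct − 0.5)`,
  with the step decaying by 0.8 at each direction reversal from 5 dB
  initially; the SRT is the mean of the last 10 sentence levels. The exact
  step rule of the clinical matrix test is not public in the source
  description ("varying step size based on word scoring"); this
  proportional-to-error rule is a configurable stand-in whose recovery
  error (≈0.4 dB MAE over 500 prototype tracks, well within the 1-dB
  acceptance band) was established before the defaults were frozen.
* **Cohorts** draw, per group, from a Gaussian copula with Gaussian
  margins. Group sizes (13 + 2 excluded / 15 / 14), ages, 4-kHz audiometric
  thresholds and SAM/RAM EFR amplitudes use the published group means/SDs;
  the pooled older-group SAM mean is split across oNH/oHI so the weighted
  pooled value (0.061 μV) is preserved, and the oNH–oHI DPOAE threshold
  separation is set to the published 20.9 dB. SRT means/SDs and per-group
  DPOAE thresholds are not published and are plausible-value configuration.
  The correlation target is built from a three-factor loading model
  (envelope-coding integrity, hearing sensitivity, general test ability) —
  positive semi-definite by construction — with the EFR_RAM × SRT_SiN-HP
  loading solved so the within-group Spearman target is exactly −0.73.
  Published pooled-cohort correlations are deliberately *not* used as
  within-group targets: pooling across groups with different means adds
  correlation of its own, so within-group targets equal to the pooled
  values would overshoot. Generator fidelity is therefore checked on
  within-group sample correlations at n = 5000 per group.

## 6. Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed, and generators
stamp their seed and parameters into their outputs; `run_pipeline()`
derives per-stage sub-seeds from one global seed and writes a manifest with
a config checksum so that identical configurations produce identical
artifacts. Test-suite problem sizes are chosen to make the statistical
assertions sharp but quick: noiseless recovery uses 8-epoch sets; bias and
calibration properties use 2048-sample epochs at 4096 Hz with 40–100
Monte-Carlo repetitions; the null-calibration and oracle-equivalence checks
run the full measurement geometry (1000 × 8192 epochs, 200 bootstrap runs,
100 seeds). The epoch-set interchange format is delimited text plus a JSON
sidecar, which round-trips the double-precision payload bit-exactly.

## 7. Known limitations

* The estimator assumes the modulation frequency is known and stable;
  frequency drift within a recording is not modelled or corrected.
* Noise-floor subtraction makes the amplitude a conservative
  (downward-biased) estimate for strong components; comparisons across
  conditions with similar floors are unaffected, absolute amplitudes carry
  the ~1–2% window-leakage bias discussed above.
* The monotone-cubic threshold model extrapolates; the 30-dB extrapolation
  bound and the walk-down root rule contain, but cannot eliminate,
  model-dependence when the criterion lies far below the measured range.
* Commonality analysis is implemented for 2–3 predictors, the sizes used in
  this analysis family.
* The cohort generator produces jointly Gaussian variables; real cohort
  variables (thresholds, SRTs) are bounded and can be skewed, which is one
  reason the analysis battery gates its correlation method on normality.
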