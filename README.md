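# ramefr

Envelope-following response (EFR) markers of cochlear synaptopathy, and the
analysis chain around them.

Cochlear synaptopathy — the loss of synapses between inner hair cells and
auditory-nerve fibers — degrades supra-threshold temporal-envelope coding
while leaving the audiogram largely intact, and is a candidate explanation
for speech-in-noise difficulties in older listeners with clinically normal
thresholds. `ramefr` implements the computational chain used to study this
question end to end:

* **Stimulus synthesis** — sinusoidally (SAM) and rectangularly (RAM)
  amplitude-modulated tones,
  `x(t) = [1 + md·sin(2πf_m t + φ)]·sin(2πf t)` and
  `y(t) = [2 + 2md·m(t)]·sin(2πf t)` with a rectangular modulator `m(t)` of
  duty cycle τ = 25%, tapered-cosine windowing, and peak-to-peak level
  matching with dB SPL bookkeeping.
* **EFR amplitude estimation** — bootstrapped averaging of polarity-balanced
  complex epoch spectra; per-harmonic noise floors from the ten flanking
  bins (five per side); peak-to-noise-floor (PtN) magnitudes at the
  modulation frequency and its first four harmonics; phase-preserving
  time-domain reconstruction; the EFR amplitude
  `EFR = (max(W̄) − min(W̄))/2` in μV, with a bootstrap SD.
* **DPOAE thresholds** — growth functions of the distortion-component level
  L_DC(L2), a bootstrapped monotonicity-constrained cubic fit, and the
  threshold TH_DP where the (extrapolated) curve reaches −25 dB SPL, with
  Scissors-paradigm primary levels (L1 = 0.4·L2 + 39), least-squares-fit
  component filtering, and Tukey-fence winsorization of outlying thresholds.
* **Cohort statistics** — normality-gated Pearson/Spearman correlations,
  Bonferroni control with explicit family sizes, the Derrick
  partially-overlapping-samples t-test for mixed paired/independent designs,
  hearing-threshold residualization, multiple regression with VIF,
  Durbin–Watson and residual-normality diagnostics, commonality
  decomposition of R² into unique and shared components, and continuous
  two-segment (knee-point) growth fits.
* **Synthetic data with known ground truth** — epoched EEG-like recordings
  (harmonic stacks in white + 1/f noise with per-epoch gain jitter), DPOAE
  growth functions, psychometric listeners driving 1-up/1-down adaptive
  speech-reception-threshold (SRT) tracks, and multivariate three-group
  cohorts (yNH / oNH / oHI) with targeted within-group Spearman correlation
  structure.

The two estimators follow the classic R modelling idiom: `efr_fit()` and
`dpoae_fit()` return classed objects with `print`, `summary`, `coef`,
`plot` (and `predict` for DPOAE fits) methods.

## Worked example

Simulate a RAM-like recording at measurement scale (1000 epochs, 500 per
polarity, 0.5-s epochs at 16384 Hz) and estimate the EFR marker:

```r
library(ramefr)
truth  <- efr_ground_truth(amplitudes = c(0.18, 0.09, 0.04, 0.015, 0.006))
epochs <- generate_epochs(truth, noise_model(white_sd = 1, pink_sd = 1),
                          n_epochs = 1000, seed = 1)
fit <- efr_fit(epochs, fm = 120, n_draws = 1000, n_boot = 200, seed = 2)
fit
#> Bootstrapped EFR amplitude estimate
#>   amplitude: 0.2180 uV (bootstrap SD 0.0021 uV, 200 runs of 1000 epochs)
#>   harmonics (Hz): 120, 240, 360, 480, 600
#>   PtN (uV): 0.1743, 0.0849, 0.0392, 0.0122, 0.0045
```

The noiseless ground truth for this harmonic stack is 0.2260 μV of half
peak-to-peak amplitude, so the estimate recovers it to within a few percent
against a 1-μV-SD noise floor; the per-harmonic PtN values recover the
generating amplitudes (0.18, 0.09, 0.04, 0.015, 0.006 μV) after noise-floor
subtraction.

Level matching of the two stimuli reproduces the measurement bookkeeping —
a RAM tone scaled to the peak-to-peak amplitude of a 70 dB SPL SAM tone
presents at 68 dB SPL:

```r
sam <- synthesize_sam(stimulus_spec(kind = "sam", level = 70))
ram <- synthesize_ram(stimulus_spec(kind = "ram"))
match_peak_to_peak(sam, ram)$matched_level
#> [1] 68.16848
```

A DPOAE growth function whose true curve crosses −25 dB SPL at L2 = 42
(1 dB of point noise) yields:

```r
growth <- generate_dp_growth(c(-25 - 42 * 1.1, 1.1), noise_sd = 1, seed = 3)
dpoae_fit(growth, n_boot = 500, seed = 4)
#> Bootstrapped DPOAE threshold
#>   TH_DP = 42.19 dB SPL (SD 0.55) at the -25 dB SPL criterion
#>   500 of 500 bootstrap draws valid
```

And the cohort battery on a simulated 44-subject cohort:

```r
co  <- generate_cohort(seed = 5)
reg <- fit_linear_models(co, "srt_sin_hp", c("efr_ram", "th_a"))
reg
#> Linear model: srt_sin_hp ~ efr_ram + th_a
#>   adj. R^2 = 0.602, F(2, 41) = 33.50, p = 2.38e-09
#> ...
commonality(co$srt_sin_hp, co[c("efr_ram", "th_a")])
#> Commonality decomposition (total R^2 = 0.6204)
#>               component     r2 pct_of_total
#>         unique: efr_ram 0.2858         46.1
#>            unique: th_a 0.0086          1.4
#>  common: efr_ram & th_a 0.3260         52.6
```

Here the RAM-EFR marker retains a substantial unique contribution to the
high-pass speech-in-noise SRT after accounting for hearing sensitivity —
the pattern the marker is designed to expose.

## Package layout

* `R/stimgen.R` — stimulus specs, SAM/RAM synthesis, windowing, matching.
* `R/efr.R` — `epoch_set`, the bootstrapped spectral chain, `efr_fit`.
* `R/dpoae.R` — growth containers, LSF filtering, monotone cubic
  bootstrap, `dpoae_fit`, winsorization.
* `R/cohort_stats.R` — the statistical battery.
* `R/synthdata.R` — all ground-truth generators.
* `R/io.R` — delimited/JSON interchange formats and `run_pipeline()`.
* `vignettes/efr-marker-methods.Rmd` — the methods vignette: model,
  assumptions, numerical choices, and limitations.
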