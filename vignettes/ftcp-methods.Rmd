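---
title: "Quantifying categorical perception with sweep frequency-tagging EEG and psychophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying categorical perception with sweep frequency-tagging EEG and psychophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ftcp` implements a complete measurement chain for studying how category
learning reshapes visual discrimination, combining a neural index — the
sweep frequency-tagging (FT-EEG) oddball response — with behavioral
psychophysics (same–different discrimination and explicit category
training).  This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not show.

## The paradigm as data

Stimuli live on a one-dimensional shape continuum (aspect ratio or
curvature), expressed as signed percent distance from the continuum
midpoint.  Three schedules drive everything downstream:

* **Sweep FT-EEG** (`build_sweep_schedule()`): base images flicker at 6 Hz
  with every fifth image replaced by an oddball (1.2 Hz).  Within a 70 s
  trial the base stays fixed at one endpoint (±99%) while the oddball steps
  through the seven assessment levels every 10 s (12 oddball cycles per
  step).  Six trials per assessment, alternating sweep direction.  At step
  1 the oddball equals the base (no oddball response, by construction); at
  step 7 it is the opposite endpoint; step 4 straddles the trained category
  boundary.
* **Same–different discrimination** (`build_discrimination_schedule()`):
  pairs 1–3 and 5–7 probe within-category sensitivity, pair 3–5
  between-category sensitivity; each of the 10 pair types (3 different
  pairs × 2 screen orders + 4 identity pairs) appears 20 times in 4 blocks
  of 50.
* **Category training** (`build_training_schedule()`): 3 × 150 trials over a
  50-level continuum (4% spacing).  Block 1 is uniform (each stimulus three
  times); blocks 2 and 3 oversample the boundary zone at 60/40 and 80/20.

Two design details are under-determined by the task description and were
fixed once as package policy:

* **Boundary zone.** Defined as the 20 training stimuli closest to the
  boundary (the inner 40% of the continuum) — symmetric, and covering the
  region where the psychometric slope is estimated.
* **Pseudorandomisation.** Schedules are shuffled and locally repaired until
  no two consecutive trials are identical, including across block
  boundaries; the procedure is seeded and deterministic.  Blocks 2–3 use
  deterministic zone counts (90/60 and 120/30) with seeded within-zone
  remainders, so the stated sampling fractions hold exactly.
* **Stimulus bins.** The 50 training levels map onto 10 bins of 5 adjacent
  levels in level order — the only partition that yields 15 responses per
  bin from a uniform 150-trial block.

## Generative model for the EEG

`simulate_sweep_recording()` produces 64-channel recordings at 512 Hz with
the statistical structure the quantification assumes:

* **Steady-state responses** are phase-locked sinusoids at the stimulation
  frequencies and their harmonics with geometric amplitude decay (default
  0.6 per harmonic, 6 harmonics).  The base response (default peak 2 µV)
  has a medial-occipital scalp profile centred on Oz; the oddball response
  (default peak 0.6 µV) an occipito-temporal profile with a right > left
  factor of 1.3, matching the right-lateralised discrimination responses
  such paradigms report.  Scalp profiles are Gaussians on an idealized
  10-20 grid layout (`biosemi64_layout()`); the grid preserves montage
  neighbourhoods but is not a digitised head model.
* **Oddball tuning.** A per-step gain in [0, 1] with `tuning[1] = 0`
  (identical oddball, no response).  `default_tuning("linear")` rises evenly
  (no categorical structure); `"categorical"` adds a boundary bump at step
  4.  The default group scenarios give NT categorical tuning at both
  assessment moments and ASC linear tuning before but categorical tuning
  after training — the qualitative group × moment structure the analysis is
  built to detect, with no claim that the gains equal the study's effect
  sizes.
* **Noise** is synthesized in the frequency domain with seeded random
  phases: amplitude spectral density `white + pink·f^(-γ/2)` (defaults
  0.02 and 0.10 µV/√Hz, γ = 1), independent across channels, band-limited
  at 120 Hz (above the analysis band).  All response frequencies are
  integer multiples of 0.1 Hz, so they land on exact analysis bins of the
  10 s windows — no leakage by construction.
* **Fades.** The 1.67 s fade-in/out ramps sit *outside* the measured 70 s
  core (events mark the core onset).  Placing them inside would attenuate
  the first and last sweep steps by roughly 8% and make exact amplitude
  recovery impossible; with ramps outside, a noiseless recording returns
  the injected amplitude to about 0.1%.

The default signal-to-noise ratio is deliberately high (single-trial
oddball z well above 10 at the profile peak).  This is a calibration
regime: it makes per-subject amplitude recovery accurate to a few percent,
which is what the recovery and scenario tests require.  Real recordings
are far noisier; passing tests demonstrate correctness of the chain, not
expected single-subject precision in an experiment.  Other realities the
generator ignores: eye blinks and other artifact transients, spatially
correlated noise, ERP onset responses, and between-channel noise
heterogeneity.

## The quantification chain

`quantify_recording()` runs, per recording:

1. **Segmentation**: 76 s segments (2 s before to 4 s after each 70 s core).
2. **Filtering**: zero-phase fourth-order Butterworth band-pass
   0.1–100 Hz.  Implemented as the forward–backward (squared) Butterworth
   magnitude response applied in the frequency domain with 10 s reflective
   edge padding; this is the same response filtfilt approximates, without
   per-channel IIR transients, and passband gain at 1.2–24 Hz is 1 within
   10⁻⁴ (verified against a pure-tone oracle).
3. **Resampling** to 256 Hz.  Decimation is expressed as spectrum folding
   inside the same FFT, which is numerically identical to picking every
   second filtered sample (property-tested).
4. **Bad-channel interpolation** (optional): unweighted mean of the three
   nearest good channels; channels inside an analysis ROI trigger a warning.
5. **Common average reference**: the across-channel mean is subtracted per
   sample.  Note that re-referencing maps a per-channel signal amplitude
   `a_c` to `a_c − mean(a)`; ground-truth comparisons must use the
   re-referenced amplitude (`injected_oddball_amplitude()`).
6. **Cropping** into seven 10 s step windows of exactly 12 oddball cycles
   (2560 samples).  A "2349 time bins" figure sometimes quoted for this
   segmentation is internally inconsistent with 256 Hz × 10 s and is not
   reproduced.
7. **Averaging** step windows across the six trials in the time domain
   (sweep direction collapsed — step *k* has the same base–oddball distance
   in both directions).
8. **Spectra**: single-sided FFT amplitudes with peak normalisation (a
   sinusoid of amplitude A reads A at its bin; bin width 0.1 Hz).
9. **Baseline correction and z-scores**: for each target bin, the 12
   surrounding noise bins are the 8 bins on each side minus the two
   adjacent bins minus the single maximum and minimum of the remaining 14
   (ties broken toward the lower index, dropping two distinct bins even in
   degenerate flat spectra).  The baseline-corrected amplitude subtracts
   the mean of these bins; the z-score divides by their sample SD (same
   bin set for mean and SD).
10. **Harmonic summation**: oddball harmonics 1–6 of 1.2 Hz excluding the
    6 Hz base frequency (five harmonics), base harmonics 6/12/18/24 Hz.
    `significant_harmonics()` enforces *consecutive* retention from the
    first harmonic — an isolated higher significant harmonic does not
    rejoin the sum — with excluded frequencies neither counting nor
    breaking the run.
11. **ROIs**: medial-occipital (Oz, Iz, O1, O2) for the base response,
    left (P9, PO7) and right (P10, P8, PO8) occipito-temporal for the
    oddball response.  `select_roi_channels()` re-derives ROIs from data:
    channels whose summed response exceeds the across-channel mean at
    one-tailed Bonferroni-corrected significance (one-sample z with the
    between-subject SD; the simplest statistic consistent with
    "significantly above the mean"), grouped into contiguous scalp
    clusters.

### Calibration of the z > 1.64 criterion

The harmonic-significance rule treats the 12 surrounding bins as a normal
sample, so z > 1.64 is nominally a one-tailed 5% test.  It is not, and the
package documents this rather than hiding it: amplitude bins of Gaussian
noise are Rayleigh distributed, the 12-bin SD estimate is both noisy
(11 df) and biased low because the max and min of the 14 candidate bins
are removed before estimating it.  Monte Carlo (see the calibration test)
puts the true exceedance rate near 0.14 for single spectra and near 0.12
even for heavily pooled, near-Gaussian spectra; the theoretical floor for
untrimmed Gaussian bins is `P(√(13/12)·t₁₁ > 1.64) ≈ 0.072`.  The
criterion is therefore liberal at the single-bin level; in practice its
damage is limited because it is applied to grand-averaged, channel-pooled
spectra where true harmonics have very large z, and because the
consecutive-run rule stops at the first miss.  The test suite asserts the
*calibrated* rate (pipeline vs an independent Rayleigh Monte Carlo); a
separate acceptance check holds the rule to its nominal 5% and is expected
to fail, deliberately, as a record of this property.

## Behavioral observers and analyses

* **Signal detection.** The same–different observer answers "different"
  with probability Φ(d′/2 − c) on different pairs and Φ(−d′/2 − c) on same
  pairs (equal-variance Gaussian model, lapse-mixed).  Same pairs carry no
  within/between label, so their decision variable uses the mean of the two
  d′ parameters; one consequence, visible in the scenario tests, is that a
  generative between-within gap of 1.0 appears as a recovered CP contrast
  of about 0.5.  `dprime()` applies the 1/(2N) correction for extreme
  proportions (the common convention; configurable).  False alarms are
  pooled across the four same pairs per block — a per-pair false-alarm rate
  is undefined for different pairs — and d′ is computed per different-pair
  type against that pooled rate.
* **CP index** (`cp_contrast()`): between-category d′ minus the unweighted
  mean of the two within-category d′.  Default scenarios: NT has a
  between-category advantage at both moments (within 1.0/between 2.0 pre,
  1.3/2.3 post); ASC starts flat (0.8/0.8) and gains the advantage only
  after training (0.9/1.9).
* **Psychometric fits** (`fit_psychometric()`): maximum binomial likelihood
  of `p(x) = 1/(1 + exp(−(x − α)/β_scale))` via the logit-link GLM —
  identical to the standard two-parameter logistic fit.  The reported
  `slope` is the steepness 1/β_scale (larger = sharper boundary); both
  parameterisations are returned.  Lapse and guess rates are fixed at 0.
  Confidence intervals come from a seeded parametric bootstrap (percentile,
  default 200 replicates).  Degenerate data (no response variation or
  separation) return `converged = FALSE` rather than an error.  A known
  consequence of the zero-lapse fit: when the generative slope is steep and
  responses saturate, a 2% generative lapse biases the fitted slope down
  and bootstrap CIs undercover (about 80% at the steepest block in our
  checks, against 95–97% in the uniform block).  The learner model draws a
  per-subject boundary (SD 6%) and per-block slopes steepening across
  blocks (means 0.06/0.10/0.14 per percent); the ASC scenario's block-1
  slope SD is 1.8 × the NT one, the ratio implied by the variance
  heterogeneity the pipeline is meant to detect.
* **Variance-ratio test** (`variance_ratio_test()`): F = var(A)/var(B) with
  (n_A−1, n_B−1) df, two-sided p; closed-form power in
  `variance_ratio_power()`.
* **Trait correlations** (`correlate_with_traits()`): Pearson r with the
  t-transform p-value on complete pairs.

## Orchestration and reporting

`run_pipeline()` runs simulate → quantify → analyse for a configured
cohort, derives every seed deterministically from the master seed, writes
tidy CSVs plus a manifest with MD5 checksums (re-running a configuration
reproduces the checksums bit for bit), and assembles the contrast tables:
neural rows restricted to the analysis steps 2/4/6 (within / boundary /
within) by occipito-temporal ROI, behavioral rows keyed by within- vs
between-category comparison.  Extreme outliers — beyond Q3 + 3·IQR or
below Q1 − 3·IQR with linear-interpolation (type 7) quartiles — are
flagged, never dropped.  Figures are qualitative analogues (per-step
amplitude curves, per-pair d′ panels, psychometric curves), not pixel
reproductions of any publication figure.

## Problem sizes used in tests and scripts

Simulation sizes are the package's own choices balancing statistical
resolution against a desk-scale run: the scenario tests use 50 simulated
subjects per group (sign tests on the CP index and on the post-minus-pre
boundary-step amplitude, full 6-trial recordings per subject and moment);
amplitude recovery uses 20 seeds at default SNR; detection calibration
uses >20 000 independent target bins from noise-only recordings;
psychometric recovery uses 200 simulated subjects at 15 responses per bin.
Property tests that do not probe trial averaging use a reduced 2-trial
sweep design.  The analysis scripts use smaller cohorts (4 neural, 38
behavioral subjects per group) so the whole workflow re-runs in a few
minutes; `scripts/acceptance.R` sits in between (8 recovery seeds, 12
neural and 40 behavioral subjects per group).

## Known limitations

* The generator's high-SNR default regime means scenario tests validate
  the measurement chain, not field-realistic detection power.
* Group scenarios are qualitative: gains and d′ values encode orderings,
  not estimated effect sizes.
* The z > 1.64 harmonic criterion is intrinsically liberal (see above).
* Mixed-effects modelling, post-hoc contrasts and Bayesian re-analysis are
  out of scope; the contrast tables are exported for external tools.
* Recordings are kept in memory and exported as plain text (events TSV,
  tables CSV); no binary EEG interchange formats are written.
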