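---
title: "Models and methods: visuocortical tuning analysis of frequency-tagged EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ssvepTuning)
```

## Overview

This package implements, end to end, the analysis of a differential fear
conditioning experiment with a generalization test, where two face stimuli
(CS+, CS−) and four morphs (GS1–GS4) flicker at 12 Hz and entrain a
steady-state visually evoked potential (ssVEP). The scientific endpoint is
the *shape* of the visuocortical response profile across the six conditions —
lateral inhibition vs quadratic vs linear generalization — and how that shape
scales with a continuous social-anxiety covariate. Because the original
recordings are not bundled, a first-class synthetic-data module generates
every input with a known ground truth; all statistics run identically on
externally supplied tables (`load_real_data()`).

## The synthetic world

The generator states one concrete world and sticks to it:

* **Design.** Three phases; habituation and acquisition with 15 CS+ and 15
  CS− trials each, generalization with 15 trials of each of six conditions —
  150 trials. Orders are pseudo-randomized by rejection sampling until no
  condition occurs more than twice in a row (attempt cap 10,000, then an
  error). 12 of 15 CS+ trials are reinforced in acquisition (80%), 6 of 15 in
  generalization (40%), none in habituation. Inter-trial intervals are
  uniform on 2000–2500 ms. The aversive US occurs at stimulus offset, outside
  the analysis window, so no US-evoked activity is synthesized.
* **Subjects.** A SPAI-like anxiety score from a truncated normal
  (M = 67.70, SD = 19.74, bounds [0, 200]; the wide bounds keep the mean
  shift from truncation below 0.1%, which the observed sample range would
  not). Each subject carries an *accentuation* — the gain with which their
  ssVEP expresses the planted pattern — linear in the standardized anxiety
  score: `acc = gamma0 + gamma1 * z(spai) + noise`, defaults
  `gamma0 = 1.2`, `gamma1 = 0.7`, `accent_sd = 0.9` (pooled-SNR units per
  unit normalized weight). These defaults plant a moderately strong pattern
  so that recovery tests at n = 40 are informative; the subtler effect sizes
  of real cohorts can be dialed in via `gamma0`/`gamma1`.
* **Montage.** A Fibonacci lattice of 129 unit-sphere sensors with one
  sensor pinned at the occipital pole; the pooling cluster is the 8 sensors
  nearest that pole. This is a deliberate idealization — no real net
  geometry, no sensor numbering — adequate because all spatial operations
  (splines, Laplacians, pooling) are geometric.
* **Epochs.** −600…+3000 ms at 250 Hz (900 samples). The driven component is
  a stationary 12 Hz sinusoid from stimulus onset with a 100 ms cosine
  on-ramp (the pre-steady-state interval is discarded by the spectral stage
  anyway), scaled by the trial condition's amplitude and by a Gaussian
  spatial profile (angular SD 0.7 rad) peaking at the occipital pole.
  Condition amplitudes follow `max(0, baseline + accent_scale * acc * w/‖w‖)`.
  Background noise is 1/f^α per channel (α = 1), with *channel-specific*
  levels (lognormal, log-SD 0.3 around 15 µV): real electrodes differ in
  impedance and noise, and without this heterogeneity distribution-based
  artifact thresholds would be unrealistically tight and flag the
  signal-bearing occipital channels. Optional artifact trials carry blocks of
  saturated channels (±500 µV) or high-gradient spikes.
* **Calibration.** `baseline = 0.45` µV and `accent_scale = 0.1` µV per
  SNR-unit were chosen so the full pipeline's pooled SNR lands at the level
  occipital ssVEP studies report (mean ≈ 3.5, SD ≈ 2): after averaging 15
  trials, pooled SNR ≈ 1 + c·amp² with c ≈ 11 at this noise level. The
  calibration targets are published descriptive statistics, fixed before any
  acceptance measurement.
* **Ratings.** Valence/arousal (1–9) and US expectancy (0–100) with a linear
  generalization gradient from CS+ to CS−, Gaussian noise, then clipping;
  habituation ratings are flat at the scale midpoint and US expectancy is
  only collected after acquisition.

What a green test does *not* establish: the generator has no real head
geometry, no volume conduction, no ocular or muscular artifacts, no
non-stationarity across the session, and its SNR sampling noise is chi-square
from the spectral estimator only. Agreement of the statistics with a planted
world is evidence of correct implementation, not of the neuroscientific
claim.

## Preprocessing

Filtering is a zero-phase low-pass with the squared magnitude of a 4th-order
Butterworth (the forward–backward equivalent), applied in the frequency
domain: gain `1/(1 + (f/40)^8)`; 12 Hz is attenuated < 0.01%, 60 Hz > 95%.
Artifact detection computes |max|, SD and the maximum temporal gradient per
trial and channel and flags a channel when any statistic exceeds
median + k·IQR (k = 3) pooled over trials and channels; a trial is rejected
when more than 20 of 129 channels are flagged. Decisions never see condition
labels. Flagged channels in retained trials are replaced by spherical-spline
interpolation (m = 4, 50 Legendre terms, ridge 1e-5); unflagged channels are
bit-identical. Averaging is the arithmetic mean over retained trials per
phase × condition; reinforced trials are included by default (the US falls
outside the spectral window) and can be excluded by flag.

## Current source density

The surface Laplacian uses Perrin-style spherical splines: solve
`(G* + λI) c = v` with a sum-to-zero constraint, where `G*` is the spline
Gram matrix scaled so its trace equals the channel count, and apply the
companion kernel whose degree-l coefficient is `l(l+1)` times larger.
λ = 0.2 by default. **Convention note:** published CSD implementations differ
in where λ enters; here it is added to the diagonal *after* trace
normalization, so the same λ is comparable across montages. The transform is
linear, reference-free (constants map to < 1e-8 of input scale), and on a
dense montage maps a degree-l spherical harmonic to `l(l+1)` times itself
within 2% — the eigenfunction property the tests pin down. Increasing λ
monotonically shrinks high-spatial-frequency output.

## Spectra and SNR

The FFT window is 500–3000 ms post-onset: 625 samples at 250 Hz, 0.4 Hz
resolution, 12 Hz exactly on bin 30 — thirty complete cycles, so no taper is
needed and leakage is nil; the window is linearly detrended. SNR divides the
12 Hz power by the mean power of the six neighbours at ±2, ±3, ±4 bins
(±0.8, ±1.2, ±1.6 Hz); the immediate neighbours are excluded. The "six
adjacent bins, excluding the two immediate neighbours" rule is read
symmetrically (three per side) — the only reading consistent with both
counts. SNR is computed per channel and then averaged over the 8-sensor
occipital cluster (pooling spectra first is available as an option), and is
invariant to global rescaling of the voltages.

## Frequentist mixed models

Each phase's table is analyzed with
`response ~ condition × covariate + (1 | subject)`, covariate mean-centered,
REML estimation. The implementation profiles the variance ratio analytically
(one-dimensional optimization, near machine precision) and reports:

* omnibus F for condition and for the interaction, with **Satterthwaite**
  denominator df via the eigen-contrast method; on the complete balanced
  designs analyzed here these equal the Kenward–Roger and classical
  repeated-measures values — (n−2)(k−1), e.g. F(5, 325) at n = 67, k = 6 —
  which the test suite verifies against a stratified-ANOVA oracle to 1e-8;
* the covariate t test as the slope *averaged over conditions*: a pure
  between-subject contrast with df = n − 2 (the raw treatment-coded
  covariate column would instead be the reference-level slope, whose
  variance mixes strata);
* simple contrasts of each condition against CS−, uncorrected, as
  treatment-coded coefficients at the covariate mean;
* semi-partial `R² = (q F / df2) / (1 + q F / df2)` with a noncentral-F
  confidence interval. For multi-df effects this formula gives, e.g., 0.0496
  at F(5,325) = 3.39 where other software variants print 0.045; the
  implemented variant is fixed and documented rather than matched to any
  particular printout (single-df values agree exactly).

Missing cells are an error — no silent dropping; the designs analyzed are
complete by construction.

## Bayesian model comparison

Each hypothesis shape enters as one predictor: the centered, L2-normalized
weight of the trial's condition. Models M1 (weights), M2 (+ covariate), M3
(+ interaction) are compared against the random-intercept-only null. Priors
are Jeffreys–Zellner–Siow: the standardized fixed-effect block shares one g
with `g ~ InvGamma(1/2, r²/2)`, r = 0.5 (Cauchy scale on standardized
slopes); the subject-intercept block has its own g with r = 1. β and σ²
integrate analytically; the remaining two g-dimensions are integrated by
deterministic quadrature on the log-g scale with a grid adapted to the
Laplace width of the integrand and an error estimate from grid halving,
reported with every BF (a warning fires if it exceeds 5% of |log BF|). The
BF is invariant to affine transformations of the weight vector — verified to
1e-8 — and a brute-force Monte-Carlo oracle (g drawn from its prior, the
conditional marginal averaged over 1e6 draws) validates the quadrature
within 5% on a small fixture. Transitive BFs between shapes are ratios of
full-precision BFs against the common null, never of rounded values.

## Tuning index, correlation BF, bootstrap BF

The visuocortical tuning index is the scalar product of a weight vector with
a subject's six condition SNRs (linear in the SNRs by construction). Its
association with the anxiety score is reported as Pearson's r with the
t test at n − 2 df, plus a Bayes factor for ρ ≠ 0 obtained by numerically
integrating the *exact* sampling density of r (hypergeometric form) against
a symmetric stretched-beta prior on ρ (κ = 1: uniform on (−1, 1)); a 10×
finer grid changes the result by < 1% (tested). Note this exact-density BF
differs numerically from JZS-regression-based correlation BFs.

The cross-phase bootstrap BF resamples the per-subject CS+ − CS− differences
of each phase B = 100,000 times, estimates the odds that the group mean
difference is positive with Laplace smoothing `(count+1)/(B−count+1)`, and
reports acquisition odds / habituation odds, repeated 100 times for a mean
and standard error (also as a percentage). Equal-length inputs share
resampling indices (common random numbers), so identical inputs give exactly
BF = 1. Limitation, inherent to the smoothed-odds definition: under
(near-)complete separation the odds saturate at B + 1 and the BF scale
depends on B; the 1/√B convergence of the SE holds at interior
probabilities.

## Numerical choices

* REML: 1-d profiled criterion, `optimize()` at tol 1e-10, explicit boundary
  check at zero subject variance (falls back to residual df when the
  information matrix degenerates).
* Satterthwaite: central finite differences of the contrast variance and of
  the REML criterion (relative step 1e-4).
* Noncentral-F inversion for R² intervals guards against `pf()` underflow at
  extreme noncentrality.
* Quadrature: per-dimension span 10 Laplace SDs (min 6), step ≤ SD/3,
  trapezoid in log-space via log-sum-exp.
* The EDF writer quantizes to 16 bits over a symmetric physical range; round
  trips are exact to the quantization step.

## Open design points resolved here

* Reinforced CS+ trials are *included* in ssVEP averages by default (US
  outside the analysis window); `exclude_reinforced` exercises the other
  reading.
* SNR uses power spectra (amplitude mode available for sensitivity checks).
* The exact SCADS parameterization is not published; the three canonical
  statistics with median + 3·IQR cutoffs preserve the documented decision
  rule (">20 of 129 channels" rejection) that downstream results depend on.
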