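---
title: "Decoding phosphene-like visual stimuli from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding phosphene-like visual stimuli from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdecode)
```

`erpdecode` is an analysis stack for a specific scientific question: are the
EEG responses to *phosphene-like* visual stimuli — solid bright shapes on a
dark background, the kind of percept electrical stimulation of the visual
pathway produces — discriminable by stimulus feature, at the single-trial
level, and how much does pooling repeated presentations help? This vignette
documents the models behind each stage, the parameters that matter, and the
design decisions taken where more than one reasonable choice existed.

## The experimental design being modelled

A subject fixates the centre of a large screen while bright gray shapes
(luminance 0.5 on black) flash for 750 ms each, separated by an
inter-stimulus interval drawn uniformly from 1–1.25 s. The default design
has two sessions of 30 sub-sessions with 50 presentations each: 3000 flashes
in total, 25 per stimulus per session for a 60-stimulus registry.

The registry lives on a 5 × 5 grid. The exact shipped composition is a
package choice (the shapes are configurable): 25 single blocks, 5
full-column and 5 full-row bars, 5 + 5 centred 1 × 3 bars, five 2 × 2 and
five 3 × 3 square blocks (four corners plus a centred one), and 5
ring/centre shapes (full 16-cell ring, 12-cell ring without corners, the 4
corner cells, a 9-cell cross and a 4-cell diamond). This composition was
chosen so that every one of the ten decoding tasks has non-empty, sensible
classes; any family can be replaced as long as that property holds —
`build_task_registry()` derives class membership from stimulus geometry, not
from hard-coded id lists.

Geometry conventions: cells are 0-based `(row, col)` with row 0 at the top
(superior visual field); "left/right" and "superior/inferior" are decided by
the stimulus centroid relative to the grid centre, with centred stimuli
excluded from the binary location tasks. The `outer_vs_middle` split uses
lit cells (all on the border ring vs none), and `outer_vs_center` opposes
large peripheral shapes (rings, corner cells, corner blocks) to small
central ones (area ≤ 4, interior, centroid at the centre) — deliberately
confounding luminosity with eccentricity, which is the point of that task.
Tasks are flagged balanced when the largest class has at most 1.5 × the
stimuli of the smallest; the flag selects the cross-validation scheme
downstream.

## The synthetic EEG generator

No public recording of this paradigm exists, so the generator is a
first-class, tested module. It emulates what the analysis needs to be
sensitive to, not cortical biophysics.

Each stimulus has a per-channel ERP template: the sum of a negative
Gaussian-windowed component at 150 ms (width 45 ms) and a positive one at
300 ms (width 60 ms). These atypical latencies — rather than classic
N70/P100 peaks — reflect how large full-field phosphene-like stimuli behave;
both are configurable. Stimulus features modulate amplitudes:

* positive amplitude grows linearly with lit area
  (`pos_base + pos_area_gain * area`, default 1 + 0.45/cell µV);
* negative amplitude decays exponentially with area
  (`neg_base * exp(-neg_area_atten * (area - 1))`, default 8 µV, 0.06/cell);
* the negative component scales up on the scalp hemisphere contralateral to
  the stimulus centroid (`laterality_gain = 0.8`) and for inferior-field
  centroids (`elevation_gain = 0.6`);
* both components decay with centroid eccentricity
  (`exp(-0.18 * grid units)`), a surrogate for the foveated retina;
* all amplitudes are weighted toward posterior channels (frontal floor
  0.25).

Background noise is per-channel independent Gaussian noise with a 1/f
amplitude spectrum (σ = 9 µV per channel), generated by spectral shaping;
optional ocular transients (off by default) are frontal-weighted smooth
bumps. The channel layout is a schematic 10-05-style cap whose posterior
rows carry the "O"/"P" identifiers the ERP channel selection expects — a
synthetic stand-in, not a measured montage.

**How the effect sizes were fixed.** The literature supporting this package
makes only qualitative claims about amplitudes (larger stimuli: larger
positive, smaller negative deflection; contralateral and inferior-field
negativity). The defaults above were calibrated once so that the binary
location task lands at roughly 65–80% single-trial accuracy at the default
noise level — the regime in which both "clearly above chance" and
"near chance" behaviour are reachable by scaling a single knob — and then
frozen. Setting the four effect gains to zero produces identical templates
for every stimulus, the zero-effect control used by the chance-recovery
tests.

**What the generator does not emulate.** Spatially correlated noise, alpha
rhythms, real artifact taxonomies, volume conduction, inter-subject
variability. Tests passing on this generator therefore demonstrate the
*correctness of the analysis machinery* (no leakage, calibrated
probabilities, correct error rates), not expected performance on real
recordings.

## Preprocessing

The chain mirrors minimal real-time-compatible preprocessing:

1. **Impedance rejection**: channels above 100 kΩ are dropped per session.
2. **Bandpass**: 0.5–30 Hz zero-phase FIR on the continuous recording.
   The design is windowed-sinc with a Hamming window; transition widths
   follow `lower = min(max(0.25 l, 2), l)` and
   `upper = min(max(0.25 h, 2), fs/2 - h)` Hz, so the half-amplitude
   (−6 dB) cutoffs sit at 0.25 and 33.75 Hz for the default band at 1 kHz.
   The filter length is `3.3 fs / min(transition)` taps, rounded up to odd;
   application is one-pass with group-delay compensation and edge
   reflection. The windowed-sinc code is in-package because the available
   FIR helper designs through a 512-point frequency grid, which quantizes a
   0.25 Hz edge visibly.
3. **Epoching**: `floor(1.05 fs)` samples starting `0.3 fs` samples before
   each onset sample (window −0.3 to 0.75 s; epoch sample 0 is exactly
   −0.3 s, 0-based indexing). Truncated epochs at recording edges are
   dropped with a warning, mirroring the handful of lost trials real
   acquisition produces.
4. **Baseline**: subtract the mean of (−0.3, −0.1) s per trial and channel.
5. **aRMS rejection**: per channel, the mean over trials of the within-trial
   RMS; channels strictly outside the Tukey fences
   (quartiles ± 1.5 IQR over channels) are dropped. Quartiles use linear
   interpolation (`stats::quantile` type 7) by default — the convention is
   configurable because at small channel counts the hinge variants can
   differ. Rejection is computed per subject over all epochs of both
   sessions pooled; whether to pool across sessions is genuinely open, and
   pooling is the declared choice.

## ERP statistics

Class ERPs are plain arithmetic means over the class's trials. Statistical
discriminability is assessed per channel with the standard cluster-based
permutation recipe, implemented in-package: pointwise one-way F across
classes at each sample; samples above the F quantile at cluster-forming
α = 0.05 (df M−1, N−M) form contiguous clusters; cluster mass is the summed
F; the null is the maximal cluster mass under label permutations (default
1024), and `p = (1 + #{null ≥ mass}) / (1 + B)`. There is no cross-channel
correction — the test runs independently per channel, as is common when the
display is per-channel significance bands. The band levels (0.05, 0.01,
0.001) are configurable since display conventions vary.

Posterior channels are selected by the literal, case-insensitive rule
"name contains O or P". The rule also catches frontal-pole names like
`Fp1`; these are flagged in an `ambiguous` attribute rather than silently
dropped, so the caller decides.

## Single-trial decoding

Epochs are vectorized channel-major; every (channel, sample) pair is an
independent feature (all channels, not only posterior ones). Z-scoring is
per *channel*, pooling all training trials and samples, with the N−1
denominator; the same parameters standardize the test fold. The classifier
is an RBF-kernel SVC (`C = 1`, `gamma = 1/n_features`) with probability
calibration on the training set only: logistic (Platt) scaling of decision
values collected by stratified internal 5-fold cross-validation, one
calibrated machine per class (one-vs-rest; a single machine for binary
tasks), probabilities normalized across machines and labels taken by
argmax. Implementation notes: the quadratic program is solved by
`kernlab::ksvm` on a Gram matrix precomputed with BLAS (orders of magnitude
faster at 10⁴ features than letting the solver evaluate the kernel
entrywise, and exactly reproducible under R's seed); hyperparameter search
is deliberately out of scope.

Balanced tasks: stratified tenfold cross-validation. Unbalanced tasks: 10
Monte Carlo iterations, each subsampling every class without replacement to
the least-represented class size and then taking a stratified 90/10
train/test split. Both the 90/10 protocol and the stratification are
declared choices — the alternatives are defensible and the functions expose
them.

Chance level is estimated by a fold-matched random decoder emitting uniform
labels over the task's M classes for exactly the real decoder's test sets.
The real-vs-random comparison is a one-sided Wilcoxon test over the 10 fold
pairs — paired signed-rank by default because the random decoder is
constructed fold-matched; the rank-sum variant is available via
`paired = FALSE`. P-values are Bonferroni-corrected for the number of
subjects; Shapiro–Wilk normality of each accuracy set is reported but never
gates the test.

## Multi-trial aggregation

Calibrated probabilities of N same-class test trials are combined as

$$p_k = \frac{\prod_{i=1}^N (p_{i,k}/p_{i,M})^{1/N}}
             {\sum_{j=1}^M \prod_{i=1}^N (p_{i,j}/p_{i,M})^{1/N}}$$

evaluated in log space after clipping at 10⁻¹² and row renormalization
(calibrated probabilities can hit exact 0). The reference class M cancels:
the rule equals the normalized geometric mean, and the package asserts that
equivalence to 10⁻¹² over random simplex inputs, along with order
invariance and dominance (a class ahead on every trial wins the aggregate).

Windows slide with stride 1 over the within-class-shuffled test set of each
fold; windows contain same-true-class trials only, because accuracy scoring
of a mixed window is undefined — this is a declared interpretation of
"sliding window over the shuffled test set". Classes with fewer than N test
trials are skipped at that N and recorded. N = 1 reproduces single-trial
accuracy by construction. The N = 15 vs N = 1 accuracy change is related to
single-trial accuracy by ordinary least squares with a t-test on the slope;
confusion matrices are row-normalized per fold and averaged.

Aggregation helps only when single-trial probabilities are informative: on
zero-effect data the curve just wanders around 1/M, which is why the
package's guidance (and its tests) condition multi-trial claims on
single-trial accuracy being above chance.

## Sensitivity maps

For one machine, `f(x) = Σ_i a_i exp(-γ ||x - x_i||²) + b`, the analytic
gradient is `∂f/∂x = Σ_i a_i (-2γ)(x - x_i) K(x, x_i)`; the map is the mean
squared partial derivative over evaluation points, averaged over the
one-vs-rest machines for multi-class decoders, reshaped channels × samples,
and reduced to spatial/temporal profiles by averaging. Maps are computed on
the training fold's (standardized) data by default; the evaluation set is an
argument because train-vs-test is not settled practice. Gradients are
verified against central finite differences to 10⁻⁴ relative error.

## Numerical and testing choices

* Problem sizes in the shipped tests are scaled (typically 16–32 channels,
  125–250 Hz, 300–600 trials) so the full suite runs in about two minutes;
  the statistics are size-invariant and the full-scale design (128 channels,
  1 kHz, 3000 trials) remains the default of the user-facing constructors.
* Null calibration of the cluster test is checked on 1000 simulated null
  datasets (2 × 30 trials × 200 samples, 500 permutations each): the
  fraction of runs with any p < 0.05 must sit within 0.05 ± 0.02.
* The EDF writer quantizes to 16 bits over a per-channel symmetric range
  with 0.01% headroom and uses the exact inverse mapping on read, so the
  round-trip error is bounded by the quantization step; recordings are
  padded to whole 1 s data records.
* Determinism: every stochastic stage (schedules, noise, fold assignment,
  calibration folds, permutations, resampling, window shuffles) draws from
  R's RNG under an explicit seed argument, and seeded helpers restore the
  caller's RNG state.
* Degenerate inputs fail loudly: empty classes, single-class training sets,
  zero-variance channels, all-channel rejections, non-finite parameters and
  probabilities all raise errors naming the offender.

## Known limitations

* The generator's independence assumptions (channels, trials) make decoding
  *easier* per unit of effect size than correlated real EEG; accuracies here
  say nothing quantitative about real subjects.
* One-vs-rest calibration differs in detail from pairwise-coupling
  probability estimates; for binary tasks they coincide.
* The cluster test is per-channel only (no spatio-temporal adjacency
  clustering, no TFCE).
* ICA-based ocular artifact removal is out of scope; the generator can
  inject ocular transients for users who want to study robustness, and the
  preprocessing chain is a sequence of plain functions into which an ICA
  step can be inserted.
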