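---
title: "Biodynamic chemosensitivity profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biodynamic chemosensitivity profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodynr)
```

## The measurement and its model

Biodynamic imaging uses intracellular motion as image contrast: coherent
light backscattered from a living tissue fragment produces a dynamic
speckle field whose intensity fluctuations carry Doppler shifts from
organelle transport, membrane undulation and cell-shape change. The
fluctuation power spectrum `S(omega)` of a healthy sample has a
characteristic shape — a low-frequency plateau, a knee (corner)
frequency, a power-law roll-off above the knee, and a flat detection-noise
floor at the Nyquist frequency of the camera. The Doppler frequency maps
to intracellular speed through the backscattering relation
`delta omega = q v` with `q = 4 pi n / lambda0`; at 840 nm in aqueous
tissue (`n = 1.33`) a speed of 1 micron/s produces a shift of about 3 Hz
(`dopplerShift()` / `dopplerSpeed()`).

The assay plates ~1 mm^3 biopsy fragments into a 96-well plate (17
vehicle-control wells, 18 per drug arm), scans all wells in a repeating
82-minute loop, records a 5.5-hour baseline (4 loops), doses, and follows
the response for 12.3 hours (9 loops). The central observable is the
drug-response spectrogram

```
D(omega, t) = log10 S(omega, t) - log10 S(omega, 0)
```

where `S(omega, 0)` is the geometric mean of the last four pre-dose loops
and `t` indexes post-dose loops. Resistant tissue under monotherapy shows
a spectral red shift — gained spectral density at low frequency, lost at
high frequency, the signature of slowed intracellular motion — while the
carboplatin + paclitaxel combination produces broadband inhibition in
both phenotypes.

The logarithm base is 10 throughout: the literature plots "logarithmic
fluctuation power spectra" without naming a base, and decade-based units
keep the dynamic-range precondition (`DR`) readable as decades.

## The synthetic generator: what it emulates and what it does not

There is no deposited raw dataset, so the package carries a first-class,
seeded generator (`simulateCohort()`) whose defaults are the study
conditions: a 50-point log-spaced frequency axis from 10 mHz to 12.5 Hz,
4 + 9 loops of 82 min, 17/18/18/18 replicate wells, and a cohort of 10
resistant + 10 sensitive training patients plus 4 metastatic specimens.
The baseline spectral model is the minimal family that realizes every
named precondition (knee, half-width, slope, floor, dynamic range):

```
S(omega) = A / (1 + (omega / omega_k)^s) + NY
```

with defaults `A = 100`, `omega_k = 0.3` Hz, `s = 1.6`, `NY = 1`. Drug
action multiplies `omega_k` by a knee factor and `A` by an amplitude
factor, both ramping linearly in loop number from 1 at the dose to an
endpoint value (`defaultResponseTable()`); the noise floor is detection
noise and is left untouched. A knee shift alone cannot raise the
low-frequency plateau, so the resistant monotherapy response pairs the
knee-down shift (endpoint 0.60–0.62) with a modest plateau gain
(1.15–1.20); this reproduces the red-shift band signs (positive mean
response in 10–100 mHz, negative in 1–10 Hz) that the band-sign tests
verify on noiseless simulations. Broadband inhibition is an amplitude
endpoint of 0.5–0.6 for the combination in both phenotypes; sensitive
monotherapy is a mild blue shift (knee endpoint 1.08–1.10).

Measurement noise is multiplicative log-normal, i.i.d. per
(frequency, loop) bin with `sigmaLog = 0.08` log10 units — chosen so that
noise becomes additive Gaussian on the log-spectrogram, which is the
domain where all downstream statistics operate. Between-patient biology
enters as a log-scale jitter of the endpoint factors (sd 0.18 for the
knee endpoint, 0.10 for the amplitude endpoint). These two numbers were
calibrated once, during development, to the design point stated for the
generator: the default cohort classifies at or above 0.85 leave-one-out
accuracy and 0.9 mixture AUC without being trivially separable (top
selected components carry z-factors of order 1–3). They were frozen
before the acceptance runs and are not tuned per seed.

Quality-control violations are injected per well from four named criteria
with probabilities (0.55, 0.45, 0.65, 0.70); since each violation halves
the data-quality weight, the expected DQ is `prod(1 - p/2) ≈ 0.25`, the
typical value of the assay. An injected brightness jump also doubles the
brightness of one random post-dose loop so the detector
(`assessDataQuality()`) finds the artifact in the trace itself; detected
and pre-flagged violations with the same name count once.

What the generator does **not** emulate: spatial structure (spectra are
already sample-averaged; no per-pixel maps), holograms or speckle images,
non-stationary baselines, immobilization chemistry differences, drug
pharmacokinetics beyond a linear ramp, or correlated noise across
frequency bins. Passing tests therefore demonstrate the statistical
machinery under the stated spectral model, not performance on real
biopsies — clinical operating numbers for this assay come from real
patient cohorts and are not reproducible from synthetic data.

## From spectrograms to features

Per patient and treatment the replicate spectrograms are averaged with DQ
weights, the DMSO vehicle-control average is subtracted (default on; average
spectrograms are conventionally reported DMSO-subtracted, and a
`dmsoSubtract` switch covers the other reading), and the result is projected onto 18
filter masks:

* **9 global masks** — tensor products of order-0/1/2 polynomials along
  the post-dose loop axis and the log10-frequency axis. We use *discrete*
  Legendre (Gram) polynomials — monomials orthonormalized against the
  actual grid inner product — rather than sampled continuous Legendre
  polynomials, because sampling breaks orthogonality on a finite grid
  while the discrete construction keeps the 9-mask Gram matrix exactly
  the identity (tested at 1e-6).
* **9 local masks** — indicators of the named rheology (10–100 mHz), mid
  (100 mHz–1 Hz) and high (1–10 Hz) bands crossed with order-0/1/2 time
  polynomials. The sub-10 mHz cell-motility band and the Nyquist bin are
  outside the display range and excluded.

Nine further features are drug-induced changes in the spectral
preconditions. `fitPreconditions()` fits the baseline model to the
pre-dose and endpoint spectra (Levenberg–Marquardt on log10 densities,
log-scale parameters for positivity) and reports NY, KNEE, HW, S, DR and
the secondary top-half-decade slope SF, plus pass-through metadata (NSD
speckle contrast, BSB brightness, NCNT sample size) that cannot be
derived from spectra alone. Scale-type quantities (KNEE, HW, NY, BSB)
difference as log10 ratios post/pre; dimensionless or already-logarithmic
ones (NSD, DR, S, SF, NCNT) as arithmetic differences — the literature
does not state the convention, and log-ratios make scale parameters
comparable across wells. Non-convergent fits impute a delta of 0 with an
`imputed` flag so the feature vector keeps its fixed length; the
unstable preconditions are retained by default rather than dropped. The
three drug blocks concatenate to the fixed 27 × 3 = 81 layout
(carboplatin, paclitaxel, combination).

## Orthogonal biomarkers, similarity, classifiers

The 18 spectrogram features per drug are strongly covariant, so each
drug block is z-scored over **training patients only** and decomposed by
SVD (`selectBiomarkers()`); correlation-type standardization was chosen
because the features have heterogeneous units. All components of all
three treatments are ranked by |z-factor|,
`z = (mean_R - mean_S) / sqrt(var_R + var_S)` — symmetric in the classes
and equal to the two-class effect size up to sqrt(2) — and the top 5 are
kept as the working feature vectors. Metastatic and test patients never
enter standardization, decomposition or ranking; their scores are
computed in the frozen training frame. Component signs follow the
largest-|loading| convention so selections are rotation-stable.

Patient similarity is correlation contrast,
`S_AB = (2 sqrt(beta) / (1 + beta)) cos(A, B)` with `beta = |A|/|B|`:
cosine similarity penalized by magnitude mismatch, motivated by
interferometric fringe contrast. The k-neighbor network (k = 3) links
each patient to its top-k similarities; top-k ties break stably by
patient order for determinism, and both the directed and
union-symmetrized adjacency are retained.

Four classifiers predict chemosensitivity on the selected features, with
resistant mapped to negative values (resistant specimens sit below
the zero line in the assay's standard prediction chart):

1. **Perceptron** — minimizes the squared-error ridge cost
   `sum [sigma(b + f.w) - y]^2 + lambda |w|^2`, `lambda = 0.1`. The
   logistic is rescaled to (-1, 1) (`tanh(x/2)`) so the ±1 targets are
   attainable and the zero threshold is meaningful. The optimizer is
   deterministic gradient descent from zero with Barzilai–Borwein step
   and backtracking, tolerance 1e-8 on the gradient norm; tests verify
   the optimum against an independent BFGS run of the identical cost to
   1e-4 in the prediction.
2. **Gibbs recurrent network** — relaxes the (training-mean-centered)
   test vector by replacing one uniformly chosen coordinate per
   iteration with the corresponding value of a training vector drawn
   with probability proportional to its inner product with the working
   vector. Negative inner products clamp to zero (probabilities must be
   non-negative; centering first makes the clamping informative). Gibbs
   chains do not converge pointwise, so the relaxed vector is the
   chain's running mean, declared converged when it moves less than
   1e-4 (max-norm) over a 50-iteration window; the prediction is the
   clamped-weight label average, which is bounded in [-1, 1].
3. **Log-likelihood** — independent per-feature Gaussians per class
   (variances floored at 1e-6 of pooled), summed log-density
   differences, squashed through the signed logistic for ensemble
   comparability (the raw score is also returned).
4. **Network** — correlation-contrast k-NN label vote, exactly
   equivalent to a brute-force top-k vote (verified exhaustively on all
   label assignments for n ≤ 6).

The ensemble mean of the four is the predicted chemosensitivity; its
standard error is the across-classifier sample SE combined in quadrature
with the root-variance of ensemble means over 8 stratified 80% training
subsets (classifier refit only — feature selection stays frozen within a
fold).

## Cross-validation and outcome evaluation

`loocv()` holds out one training patient at a time and refits
standardization, SVD and selection inside every fold; metastatic and
test patients are predicted by the full-training model. Each per-class
set of (mean, SE) predictions defines an equal-weight Gaussian mixture
(`mixturePdf()`, component sigma floored at 0.02 to avoid delta
functions), with metastatic specimens scored in the R-class regardless
of clinical label. The ROC integrates the continuous mixtures over a
dense threshold grid — less threshold-sensitive than counting discrete
calls — and reports AUC (trapezoid; tested against a 10^6-draw
Monte-Carlo oracle to 0.01), the fixed-zero and Youden-optimal decision
points with sensitivity, specificity, accuracy, PLR, NLR, PPV, NPV
(prevalence from cohort counts), and the mean class separation with a
Gaussian 1.96-sigma interval whose class SEs combine between-patient
variance with per-patient ensemble SEs.

## Numerical choices and problem sizes

* Default problem sizes: 24-patient cohort × 71 wells × 13 loops × 50
  frequencies (~1.1 M spectral samples); a full pipeline run takes a few
  seconds and the LOOCV some 20 ensemble fits. Test fixtures use a
  7-patient, 12-well cohort, which exercises every code path at a
  fraction of the cost.
* Degenerate inputs: constant intensity series yield a zero spectrum
  plus the configured floor; zero feature vectors are rejected by the
  similarity measure; folds that lose a class are skipped with a
  warning; an all-zero Gibbs weight vector falls back to the unrelaxed
  test vector with a warning.
* Determinism: one master seed drives named per-stage substreams
  (cohort simulation, per-fold classifier streams), so `runPipeline()`
  is bit-reproducible for a given seed.

## Known limitations

The generator's phenotype responses are linear ramps of two spectral
parameters — real drug responses are richer in time and frequency. The
SVD component *indices* selected on synthetic data have no reason to
match those reported for the clinical cohort (they depend on the real
covariance structure), and no attempt is made to reproduce the
supplementary raw-biomarker table. NSD, BSB and NCNT are metadata-level
pass-throughs here; on real data they derive from raw images that this
pipeline deliberately does not model.
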