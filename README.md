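# biodynr

Chemosensitivity profiling of living tumor biopsies from Doppler
fluctuation spectroscopy (biodynamic imaging).

## The problem

Ex vivo biodynamic assays measure how a drug changes intracellular
motion in ~1 mm³ living biopsy fragments: coherent backscattered light
produces dynamic speckle whose fluctuation power spectrum S(ω) carries
Doppler shifts from organelle transport and membrane dynamics
(Δω = qv, q = 4πn/λ₀ — at λ₀ = 840 nm, 1 µm/s ≈ 3 Hz). Platinum-resistant
and platinum-sensitive ovarian-cancer tissue respond differently:
resistant tissue under carboplatin or paclitaxel monotherapy shows a
spectral *red shift* (slowed motion), while the combination produces
*broadband inhibition* in both phenotypes. `biodynr` implements the full
analysis pipeline that turns per-well spectra into a per-patient
resistant/sensitive call:

1. **Drug-response spectrograms** D(ω,t) = log₁₀S(ω,t) − log₁₀S(ω,0),
   referenced to the geometric-mean baseline of the last 4 pre-dose
   loops, with data-quality weights DQ = 2^(−m) (halved per violated
   quality criterion), DQ-weighted replicate averaging and DMSO
   vehicle-control subtraction.
2. **Biomarkers** — 18 spectrogram projections onto orthonormal global
   (Legendre time × log-frequency) and local (band × time) filter masks
   plus 9 drug-induced precondition changes (knee frequency, roll-off
   slope, noise floor, dynamic range, ...), concatenated over three
   treatments into an 81-element feature vector per patient.
3. **Feature selection** — per-treatment SVD orthogonalization and
   z-factor ranking, z = (μ_R − μ_S)/√(σ_R² + σ_S²), top-5 components.
4. **Similarity network** — correlation contrast
   S_AB = (2√β/(1+β))·cos(A,B), β = |A|/|B|, with a k = 3 neighbor graph.
5. **Ensemble classifier** — ridge perceptron, Gibbs-sampling recurrent
   network, Gaussian log-likelihood and k-NN network vote, averaged,
   with leave-one-out cross-validation and Gaussian-mixture ROC
   reporting (AUC, fixed-zero and Youden decision points, sensitivity,
   specificity, PLR/NLR, PPV/NPV, mean class separation).

No raw data accession exists, so the package ships a seeded synthetic
cohort generator whose defaults emulate the study conditions (82-min
loops, 5.5 h baseline + 12.3 h response, 17/18/18/18 replicate wells,
metastatic specimens that carry the resistant signature regardless of
clinical label). See the methods vignette
(`vignettes/biodynamic-chemosensitivity.Rmd`) for the models,
parameters and limitations.

## Worked example

```r
library(biodynr)
res <- runPipeline(bdiConfig(), seed = 1)   # 10 R + 10 S + 4 metastatic
r <- res$report
```

This simulates the default cohort (24 patients × 71 wells × 13 loops ×
50 frequencies), extracts features, selects biomarkers, and runs the
leave-one-out ensemble. With seed 1 it prints:

```
AUC 0.946 | LOOCV accuracy 0.90 | separation 1.43 [0.98, 1.89]
fixed-zero: sens 0.89 spec 0.87 acc 0.88 PLR 7.1 NLR 0.12 PPV 0.91 NPV 0.85
optimal (thr 0.23): sens 0.94 spec 0.84 acc 0.90 NLR 0.08
metastatic R-class: 4 / 4
   component   treatment index     z
      BM1tax  paclitaxel     1  1.78
     BM1carb carboplatin     1  1.30
 BM2tax+carb combination     2  0.92
```

Read: the mixture-model ROC has AUC 0.946; 90% of training patients are
correctly called at the zero threshold; the two phenotype classes are
separated by 1.43 prediction units; **all four metastatic specimens are
assigned to the resistant class** even though half carry a sensitive
clinical label — the generator builds in the observation that metastatic
tissue behaves dynamically resistant. The selected biomarkers (`BM1tax`
etc., the per-treatment SVD components with the largest |z|) will differ
per seed. Per-patient predictions with error bars are in
`res$predictions`; pass `outDir =` to write every stage's artifact
(feature table, similarity matrix, network edge list, ROC curve,
`report.json`).

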