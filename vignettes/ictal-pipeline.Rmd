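---
title: "Multi-band feature engineering and seizure-type classification with ictalfeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-band feature engineering and seizure-type classification with ictalfeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the pipeline

ictalfeat classifies the *type* of an epileptic seizure — absence (ABSZ),
complex partial (CPSZ), focal non-specific (FNSZ), generalized non-specific
(GNSZ), tonic-clonic (TCSZ), tonic (TNSZ) — from multichannel ictal EEG.
Clinical seizure corpora are access-restricted, so the package ships a
synthetic generator that reproduces the *structure* of such a corpus
(sampling rate, durations, class imbalance, band-specific spectra) and lets
every downstream stage be exercised and tested end to end.

The pipeline is:

1. **Preprocess.** Resample to the 250 Hz working rate, band-pass
   0.5–100 Hz, decompose into the five classical EEG bands
   (δ 1–4, θ 4–7, α 8–12, β 13–30, γ 30–80 Hz), then slice into 1 s windows
   advanced by 0.5 s (50% overlap). Trailing partial windows are dropped:
   a recording of `n` samples yields `floor((n - 250) / 125) + 1` segments.
2. **Features.** On each band-filtered window, per channel, 13 features:
   four population moments (mean, variance, skewness, *excess* kurtosis),
   sample entropy, five db4 wavelet energies, the rescaled-range Hurst
   exponent, and Hjorth mobility and complexity. Channel values are
   averaged, giving a 65-dimensional vector per segment
   (5 bands × 13 features, band-major names such as
   `gamma_hjorth_complexity`). Columns are z-scored.
3. **Selection.** Mutual information between each feature and the class
   label, estimated with a nearest-neighbour estimator for continuous
   variables against discrete labels; the top k = 30 features are retained.
4. **Classification.** Stratified 10-fold cross-validation over segments
   with per-model imbalance handling (balanced class weights for SVM, DT,
   RF; SMOTE for KNN; inverse-class-frequency sample weights for XGBoost),
   plus a feature-free null model.
5. **Evaluation and report.** Accuracy, support-weighted precision, recall,
   F1, weighted one-vs-rest AUC; pooled confusion matrices and the 5 × 13
   MI heatmap, each with a CSV twin.

# The feature set, precisely

All moments are population (1/N) moments; kurtosis subtracts 3. A
zero-variance window returns skewness and kurtosis 0 so the feature matrix
is NaN-free by construction.

**Sample entropy** follows the Richman–Moorman conventions: Chebyshev
distance, self-matches excluded, both the m-length count B and the
(m+1)-length count A taken over the same N − m templates, and
SampEn = −ln(A/B). Defaults m = 2, r = 0.2 × SD of the *same band-filtered
window being scored* — so the feature is invariant to positive rescaling of
the signal. When A = 0 the estimate is capped at
ln((N−m)(N−m−1)) − ln 2; a constant window returns 0.

**Wavelet energies** come from a 4-level Daubechies-4 decomposition written
for this package (no R wavelet package is available in the supported
dependency set); its symmetric and periodization boundary modes agree
coefficient-for-coefficient with PyWavelets, which the test suite uses as a
frozen independent oracle. E0 is the energy of the level-4 approximation;
E1..E4 are the detail energies from coarsest to finest. This E-index ↔
coefficient-set mapping is a documented package convention. Symmetric
padding is the default; periodization makes the transform orthonormal for
even lengths and is used in the energy-conservation tests.

**Hurst exponent**: for each scale τ = 2..20, split the window into
⌊N/τ⌋ non-overlapping blocks, average each block's rescaled range R/S
(range of cumulative mean-deviations over sample SD, zero-SD blocks
skipped), and take the least-squares slope of log mean R/S versus log τ.
No small-sample (Anis–Lloyd) correction is applied; the estimate is clipped
to [0, 1.5] and a constant window returns 0.5.

**Hjorth parameters** use population variances of first and second
differences: mobility = √(Var(Δx)/Var(x)), complexity =
√(Var(Δ²x)/Var(Δx)) / mobility. For a sampled sinusoid of frequency f,
mobility is exactly 2 sin(πf/fs) — one of the analytic checks in the test
suite — and for iid noise it approaches √2.

**Channel aggregation.** A multichannel segment must yield *one* 65-vector.
The package computes features per channel and averages them (configurable:
`median` or `single:<i>`), which keeps the printed dimensionality for any
montage.

# Mutual-information selection

For continuous X and discrete Y the package uses the nearest-neighbour
estimator I = ψ(N) − ⟨ψ(N_y)⟩ + ψ(k) − ⟨ψ(m_i)⟩, with d_i the distance to
the k-th nearest *same-class* neighbour and m_i the number of points of any
class strictly within d_i (k = 3 by default). Negative estimates are
clipped at zero. Ties are broken by a tiny seeded jitter with SD
1e-10 × max(1, mean |x|); the max(1, ·) guard exists because standardized
columns have mean ≈ 0 and a literally mean-proportional jitter would vanish.
The jitter RNG is reseeded per column, so duplicated columns score
identically and whole scoring passes are bit-reproducible. On coarsely
discretized data the estimator tracks the exact plug-in
Σ p(x,y) log p(x,y)/(p(x)p(y)) within 0.05 nats (tested over 20 seeds).

Selection sorts scores descending, breaking ties by ascending feature name.
By default scoring and selection run *inside each training fold*
(leakage-safe); `cv_mode = "paper_compat"` reproduces the
once-per-dataset global ordering instead. The 5 × 13 heatmap is always
produced from a global descriptive pass — it is a visualization, not part
of the fitted pipeline.

# Cross-validation and imbalance handling

Folds are stratified by class (per-class counts differ by ≤ 1 across the
10 folds) at the *segment* level: segments of one recording may land in
different folds, mirroring the segment-wise design this package follows.
That design is optimistic about generalization to unseen recordings;
group-aware CV by `recording_id` is a straightforward extension but is not
the default here.

Balanced class weights are n_total / (n_classes × n_c). SMOTE synthesizes
minority rows as convex combinations toward a same-class nearest neighbour
and is applied to training rows only, as are standardization and MI
selection in the default mode (a test plants an outlier column touching
only held-out rows and asserts the training-fold selection is unchanged).
LightGBM and CatBoost specifications exist but raise a named
model-unavailable error when their libraries are absent; `run_cv()` records
the skip and continues, so the model roster degrades gracefully across
installations.

The null model assigns each held-out segment a uniform Dirichlet(1,…,1)
probability vector. Its weighted one-vs-rest AUC is 0.5 and its argmax
accuracy 1/6 in expectation — the package's feature-free baseline. (A
uniform-guessing accuracy far below 1/6 is not reproducible from the
model's definition; only the AUC is treated as a checkable quantity.)

Weighted one-vs-rest AUC is computed from the midrank (Mann–Whitney)
statistic per class and averaged with support weights, matching the
weighted treatment of precision/recall/F1; classes absent from the truth
are excluded with renormalized weights, and a constant probability column
for a present class scores 0.5 by the midrank convention.

# The synthetic generator

Each seizure-type profile fixes: relative power in the five bands, an
optional spike-wave fundamental (a harmonically sharpened sinusoid), an
expected rate of Gaussian-windowed 40–70 Hz bursts, an RMS amplitude, and a
white-noise floor. A recording is the sum of per-band filtered Gaussian
noise (amplitudes √band_power), those transients, and sensor noise;
channels mix a shared and an individual realization with weight 0.5 so that
channel averaging in the feature stage is not a no-op. Determinism: one
global seed, per-recording seeds derived as seed + index.

The default profiles are engineered stand-ins, not clinically validated
templates: the absence profile carries the classical 3 Hz spike-wave with
δ/θ dominance, the tonic profile is γ-dominant low-voltage fast activity,
and so on. They make the six classes separable by exactly the features the
package extracts. Consequently, passing end-to-end tests demonstrates that
the implementation carries class signal through extraction, selection and
classification — it says nothing about accuracy on clinical EEG, where
class overlap, artifacts, and inter-patient variability dominate.

The generator's reference imbalance is 100/78/100/47/100/47 recordings for
FNSZ/ABSZ/CPSZ/TCSZ/GNSZ/TNSZ (472 total) with durations 14.66–202.68 s by
default. For routine analysis and testing the package uses `demo_corpus()`:
the same imbalance pattern scaled to 96 recordings of 12–26 s
(≈ 3,300–3,700 segments), a size chosen once as a realistic desk-scale
study; the null-model evaluation uses a 103-recording, 40–60 s variant
(> 10,000 segments). These sizes are stated here because they define the
conditions under which the package's own checks run.

# Numerical choices and edge cases

* FIR filters are windowed-sinc (Hamming), transition bandwidth
  min(max(0.25 × edge, 2 Hz), room) at each edge, length 3.3/Δf rounded up
  to odd; applied once with reflection padding and group-delay
  compensation, so the net phase shift is zero (verified by a
  cross-correlation-peak test). The −6 dB cutoffs sit exactly at the band
  edges with the transition band straddling each edge, so a tone one half
  transition band outside a band is already in the ~−53 dB stop band —
  this is what makes neighbouring bands cleanly separable despite the
  narrow printed edges. The 7–8 and 12–13 Hz gaps between bands are
  preserved as-is.
* Windows and steps are converted to samples by rounding; 1 s / 0.5 s at
  250 Hz is exactly 250 / 125 samples.
* Resampling is polyphase (`signal::resample`) with the rational rate
  reduced by a GCD; output length is forced to round(n × target/fs).
* EDF I/O is a minimal 16-bit implementation written here (no R EDF package
  is available in the supported dependency set); quantization bounds the
  round-trip error at one step of the per-channel amplitude range. The
  delimited-text + JSON-sidecar format is lossless.
* Degenerate inputs follow fixed conventions (documented above) so no stage
  emits NaN/Inf; `extract_features()` additionally hard-fails if any
  non-finite value survives.

# Limitations

* The generator does not model artifacts (eye blink, EMG, electrode drift),
  inter-patient variability, or physiologically realistic seizure dynamics;
  results on it are a software correctness statement, not a clinical one.
* Segment-level CV lets segments of one seizure span folds; accuracy
  estimates are optimistic relative to recording-level splits.
* LightGBM and CatBoost are specified but only runnable where their R
  packages exist.
* MI selection is plain top-k: redundancy among selected features is not
  penalized.
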