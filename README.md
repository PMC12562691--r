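# ictalfeat

Segment-wise, multi-band EEG feature engineering and seizure-type
classification in R.

## The problem

Epilepsy presents as distinct seizure types — absence (ABSZ), complex
partial (CPSZ), focal non-specific (FNSZ), generalized non-specific (GNSZ),
tonic-clonic (TCSZ), tonic (TNSZ) — and treatment depends on telling them
apart. Manual EEG review is slow and subjective, and clinical seizure
corpora are access-restricted. `ictalfeat` is for researchers who want a
tested, reproducible implementation of the segment-wise multi-band
classification pipeline: it ships a synthetic labeled ictal-EEG generator
with class-specific spectral structure, so every stage can be developed,
exercised and benchmarked without restricted data, and real recordings
(EDF or delimited text) can be swapped in through the same manifest
interface.

## The method

EEG is resampled to 250 Hz, band-passed 0.5–100 Hz, decomposed with
zero-phase FIR filters into the five classical bands — δ (1–4 Hz),
θ (4–7), α (8–12), β (13–30), γ (30–80) — and sliced into 1 s windows with
a 0.5 s step. Each band-filtered window yields 13 features:

* moments: μ = (1/N)Σxᵢ, σ² = (1/N)Σ(xᵢ−μ)², skewness γ₁, excess
  kurtosis γ₂;
* sample entropy SampEn(m, r, N) = −ln A_m(r)/B_m(r) with m = 2,
  r = 0.2·SD (Chebyshev distance, self-matches excluded);
* five Daubechies-4 wavelet energies Eⱼ = Σₖ c²ⱼₖ from a 4-level
  decomposition;
* the rescaled-range Hurst exponent H (slope of log mean R/S vs log τ,
  τ = 2..20);
* Hjorth mobility √(Var(Δx)/Var(x)) and complexity
  √(Var(Δ²x)/Var(Δx))/mobility.

Five bands × 13 features give a 65-dimensional standardized vector per
segment. Mutual information I(X;Y) between each feature and the class
label, estimated by a k-nearest-neighbour method for continuous features
against discrete labels, ranks the features and the top k = 30 are kept.
Classifiers (SVM, KNN, decision tree, random forest, XGBoost — plus
LightGBM/CatBoost specs where their libraries exist — and a feature-free
null model) are evaluated under stratified 10-fold cross-validation with
per-model imbalance handling: balanced class weights
n/(n_classes · n_c), fold-wise SMOTE for KNN, inverse-class-frequency
sample weights for XGBoost. Metrics are accuracy, support-weighted
precision/recall/F1, and weighted one-vs-rest ROC AUC from the midrank
statistic.

## Worked example

```r
library(ictalfeat)
library(dplyr)

corpus <- simulate_corpus(
  counts = c(FNSZ = 6, ABSZ = 5, CPSZ = 6, TCSZ = 4, GNSZ = 6, TNSZ = 4),
  duration_range_s = c(8, 14), seed = 3)
corpus
#> # A tibble: 31 × 6
#>    recording_id label    fs duration_s n_channels recording
#>    <chr>        <chr> <dbl>      <dbl>      <int> <list>
#>  1 FNSZ_0001    FNSZ    250       9.01          2 <eg_rcrdn>
#>  2 FNSZ_0002    FNSZ    250      12.8           2 <eg_rcrdn>
#>  # ... 29 more rows

features <- extract_features(corpus)
dim(features)
#> [1] 630  68     # 630 segments; 3 metadata + 65 feature columns

std <- standardize_features(features)
scores <- mi_score_all(std$features, seed = 1)
scores |> arrange(desc(mi)) |> head(5)
#> # A tibble: 5 × 4
#>   feature                band  feature_type        mi
#>   <chr>                  <chr> <chr>            <dbl>
#> 1 gamma_variance         gamma variance          1.42
#> 2 gamma_wavelet_energy_3 gamma wavelet_energy_3  1.30
#> 3 gamma_wavelet_energy_4 gamma wavelet_energy_4  1.26
#> 4 delta_variance         delta variance          1.08
#> 5 delta_wavelet_energy_1 delta wavelet_energy_1  1.01

sel <- select_top_k(scores, k = 30)
length(sel$selected)
#> [1] 30

cv <- run_cv(features, list(model_spec("XGBoost"), model_spec("Null")),
             n_folds = 10, seed = 2)
glance(cv) |> select(model, accuracy, f1, auc, pooled_auc)
#> # A tibble: 2 × 5
#>   model   accuracy    f1   auc pooled_auc
#>   <chr>      <dbl> <dbl> <dbl>      <dbl>
#> 1 XGBoost    0.989 0.989 1          1.000
#> 2 Null       0.132 0.130 0.481      0.480
```

Reading the output: MI scores are in nats — on this corpus γ-band power
features carry the most label information, exactly the structure the
generator plants (the tonic profile is γ-dominant). XGBoost separates the
six synthetic classes almost perfectly (fold-mean accuracy 0.989, AUC
≈ 1.0), while the feature-free null model sits at chance (accuracy ≈ 1/6,
AUC ≈ 0.5) — the pair brackets what the features contribute. Accuracy this
high reflects the deliberately separable synthetic profiles, not expected
clinical performance.

`autoplot()` renders the pooled confusion matrix of any fitted model and
the 5 × 13 band-by-feature MI heatmap; `run_pipeline()` chains every stage
and writes features, selection, metrics, figures and their CSV twins to a
report directory. A thin command-line front end with `simulate`,
`extract`, `select`, `evaluate` and `run` subcommands lives at
`inst/cli/ictalfeat.R`.

## Scope notes

The synthetic profiles are engineered stand-ins, not clinically validated
seizure templates; see the methods vignette (`vignettes/ictal-pipeline.Rmd`)
for the signal model, estimator conventions, numerical choices and
limitations.
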