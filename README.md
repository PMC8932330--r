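# fatiguefuse

Estimation of exercise-induced fatigue states from fused ECG and surface-EMG
features.

During rehabilitation exercise, muscle fatigue shows up in two places at
once: the surface electromyogram (sEMG) — amplitude grows, the power
spectrum compresses towards low frequencies — and the electrocardiogram
(ECG) — the RR interval shortens and the LF/HF balance of heart-rate
variability shifts. Either signal alone classifies the three coarse fatigue
states (relaxed = −1, transition = 0, tired = +1) imperfectly; combined,
they are complementary. `fatiguefuse` implements a feature-fusion
classifier for this setting, plus everything needed to study it end to end
without access to clinical recordings.

The core method: each labeled 30 s window of 1 ECG + 2 sEMG channels
(2 kHz) is reduced to 11 features — an ECG block
(mean RR, LF power, LF/HF) and an sEMG block (IEMG, RMS, mean power
frequency MPF, median frequency MF, per channel). A fusion coefficient
vector *d* (length 11, `d_k ≥ 0`, `Σ d_k = 11`) weights the standardized
features elementwise, and a one-vs-one ensemble of three soft-margin SVMs
with RBF kernel `φ(x, z) = exp(−‖x − z‖²/σ²)` classifies the fused vector.
*d* is optimized by a particle swarm (inertia ω = 0.8, learning factors
c₁ = c₂ = 0.5, expected-fitness termination h_e = 0.95) whose fitness is
the recognition rate of the fused classifier on an inner validation split.
Models are compared under stratified Monte Carlo cross-validation against
BPNN, KNN and LDA baselines and against single-modality variants.

Because real recordings of this kind are private, the package includes a
first-class synthetic generator with analytic ground truth (template-beat
ECG with sinusoidal RR modulation; band-shaped noise sEMG; powerline,
baseline-wander, ECG-bleed and wideband contaminants), and a preprocessing
chain: zero-phase low-pass filters, an adaptive LMS 50 Hz notch, and
denoising of the initial empirical-mode-decomposition components by db4
wavelet thresholding.

## Worked example

```r
library(fatiguefuse)

# 20 labeled 30 s windows per state, seeded
records <- generate_dataset(n_per_state = 20, window_s = 30, seed = 1)
feats   <- extract_feature_table(lapply(records, preprocess_record,
                                        emd_denoise = FALSE))

# train the fusion classifier
fit <- fit_ipso_svm(as.matrix(feats[, feature_names()]), feats$label,
                    cfg = swarm_config(q = 50, max_iter = 50, seed = 2))
print(fit)
#> <ipso_svm> 11 features, 50 PSO iterations, inner fitness 0.9444
#> fusion coefficients:
#>  [1] 0.049 0.787 0.392 1.681 1.907 0.635 1.439 0.667 1.917 0.779 0.746

# paired comparison: ECG-only vs sEMG-only vs fused, identical splits
cmp <- compare_modalities(feats, n_rep = 10, seed = 3)
print(cmp$table)
#>   modality   relaxed transition     tired      mean
#> 1      ecg 0.9833333  0.6333333 0.4833333 0.7000000
#> 2     semg 0.8833333  0.7166667 0.9333333 0.8444444
#> 3    fused 1.0000000  0.7500000 0.8833333 0.8777778
```

The rates are fractions of correctly identified test windows (per state and
overall, averaged over the Monte Carlo splits). The pattern above is the
point of the method: ECG-only separates the relaxed state almost perfectly
but collapses on tired vs transition, sEMG-only is weakest on the
relaxed/transition side, and the fused model dominates both overall because
the particle swarm assigns trust where each block is informative.

A thin command-line wrapper is installed with the package
(`inst/cli/fatiguefuse.R`) with `run`, `synthgen`, `features`, `train`,
`predict` and `evaluate` subcommands, and `run_pipeline()` drives the same
stages from one YAML configuration.

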