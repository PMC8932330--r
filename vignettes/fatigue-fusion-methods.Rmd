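---
title: "Fatigue-state estimation from fused ECG and sEMG features: models and methods"
author: "fatiguefuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fatigue-state estimation from fused ECG and sEMG features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During lower-limb rehabilitation exercise (e.g. Pilates), muscle fatigue
changes both the muscle's electrical activity and the autonomic control of
the heart. Surface electromyography (sEMG) carries the classical fatigue
signatures — amplitude growth (motor-unit recruitment) and spectral
compression (conduction-velocity drop) — but is noisy and unstable on its
own. The electrocardiogram (ECG) adds complementary information through
heart-rate and heart-rate-variability (HRV) changes. `fatiguefuse`
implements a three-state classifier (relaxed = -1, transition = 0,
tired = +1) that fuses one ECG channel and two sEMG channels (right
semitendinosus, left tibialis anterior), all sampled at 2 kHz.

The pipeline is: synthetic or recorded 30 s windows → preprocessing →
11 fatigue features → particle-swarm-optimized feature fusion → one-vs-one
RBF-SVM → Monte Carlo cross-validated recognition rates.

## Preprocessing

Each channel passes, in fixed order:

1. **Zero-phase Butterworth low-pass** (order 4, applied forward-backward):
   100 Hz for ECG, 500 Hz for sEMG. Zero-phase filtering avoids shifting
   R-peak times. Signals are extended by even mirroring before filtering;
   the pad length is derived from the slowest filter pole so startup
   transients decay below 1e-9 inside the pad.
2. **Adaptive 50 Hz notch**: a reference-free LMS canceler with an
   internally generated quadrature reference per harmonic (50/100/150 Hz by
   default, step size `mu = 0.01`). The canceler runs twice — the converged
   weights of the first pass initialize the second — so the adaptation
   transient does not leak interference into the output. A fixed zero-phase
   biquad notch (`method = "iir"`, 1 Hz bandwidth) is available as a
   fallback; it matches the LMS canceler in steady state but rings near
   window edges, which is why the LMS variant is the default.
3. **EMD + wavelet denoising**: the signal is decomposed by empirical mode
   decomposition (cubic-spline envelopes through mirrored extrema, Cauchy
   stopping criterion 0.2, at most 12 sifts per component). The first
   `n_initial_imfs = 3` intrinsic mode functions — which at 2 kHz carry most
   of the wideband noise — are soft-thresholded in a db4 wavelet basis
   (4 levels, universal threshold with a robust MAD noise estimate) rather
   than discarded, and the signal is rebuilt from thresholded components,
   remaining components and residue. With thresholding disabled the
   decomposition reproduces the input to machine precision by construction.

The wavelet transform is the periodized orthogonal pyramid; inputs are
mirror-padded to a multiple of `2^level` and truncated after
reconstruction. Supported wavelets: haar, db2, db4 (default db4).

## The 11 features

All spectral quantities come from one Welch estimator (Hann window, 50%
overlap, 1024-sample segments for sEMG) so they are mutually consistent.

* **ECG block (3)** — from the RR-interval series of detected R peaks:
  mean RR interval (s); LF band power of the RR tachogram (0.04–0.15 Hz);
  LF/HF ratio with HF = 0.15–0.40 Hz (the conventional HRV bands; the HF
  band is a package choice). The tachogram is cubic-spline interpolated to
  4 Hz before spectral estimation. A zero HF power raises an error rather
  than silently returning 0.
* **sEMG block (4 × 2 channels)** — IEMG `sum(|x|)/fs` (mV·s), RMS (mV),
  mean power frequency (spectral centroid, Hz), and median frequency (the
  half-power frequency with linear interpolation between bins, Hz).

R peaks are detected with a derivative-energy method: 5–15 Hz band-pass,
differentiate, square, 150 ms moving integration, adaptive threshold at a
quarter of the 98th percentile, 200 ms refractory period, and refinement to
the local band-passed maximum. On clean synthetic ECG the detector recovers
ground-truth beats to ~1 ms.

Feature order is frozen (`feature_names()`): the ECG block (a = 3) then the
sEMG block (b = 8).

## The fusion classifier

Features are z-scored with training-set statistics — without this, weights
on quantities measured in seconds, hertz and millivolt-seconds would be
meaningless. A fusion coefficient vector `d` of length a + b = 11, with
`d_k >= 0` and `sum(d) = 11`, multiplies the standardized features
elementwise; the weights act as per-feature trust degrees. Classification
uses a one-vs-one ensemble of three binary soft-margin SVMs (state pairs
(-1,0), (-1,1), (0,1)) with the RBF kernel
`phi(x, z) = exp(-||x - z||^2 / sigma^2)`; each sub-model is trained by a
sequential-minimal-optimization solver for the dual quadratic program
(maximal-violating-pair working-set selection, KKT tolerance 1e-6 for final
models, 1e-3 inside the swarm's fitness evaluations). Votes are combined by
majority; ties break deterministically by the largest summed absolute
decision value, then the lowest state label.

The coefficients are found by particle swarm optimization: swarm size `q`,
inertia `omega = 0.8`, learning factors `c1 = c2 = 0.5`, per-dimension
velocity clamp `v_max = 2`, positions re-projected onto
`{d >= 0, sum(d) = 11}` (clip negatives, rescale) after every update. The
fitness of a particle is the recognition rate of an SVM trained on the
fused inner-training split and evaluated on an inner validation split; the
swarm stops when the global best reaches the expected fitness `h_e = 0.95`
or after `max_iter` iterations. The final model is retrained on the whole
training set with the optimal coefficients.

Design choices worth stating explicitly:

* **Leakage-free fitness.** Fitness is evaluated on a stratified 70/30
  split *inside* the training set, so the outer test data never influence
  the fusion coefficients.
* **Hyperparameters.** `C = 10` and `sigma = sqrt(11)` (kernel width of the
  order of the expected inter-point distance of standardized 11-dim data)
  are defaults, exposed in every interface.
* **Constraint handling.** The sum constraint is enforced by projection
  after every position update, keeping the swarm on the surface where the
  weights are interpretable as a distribution of total trust.
* **Study-scale profile.** The desk-scale defaults are `q = 50`,
  `max_iter = 50`; a study-scale profile (`q = 2000`) is available through
  the configuration but is two orders of magnitude slower for no change in
  the qualitative behavior at the data sizes used here.

## The synthetic-data generator

Real recordings of this kind are rarely shareable, so the package ships a
seeded generator whose ground truth is analytic:

* **ECG**: a fixed sum-of-Gaussians PQRST template placed at beat times
  whose RR series is `rr_mean + lf_amp*sin(2*pi*0.1*t) +
  hf_amp*sin(2*pi*0.25*t)`. Deterministic sinusoidal modulation at the LF
  and HF band centers makes the LF/HF ground truth a closed form
  (`lf_amp^2 / hf_amp^2`). True beat times and the noise-free waveform are
  stored alongside the signal.
* **sEMG**: Gaussian noise shaped by a 4th-order Butterworth band-pass
  centered on the state's spectral center (edges at 0.5x/1.5x), scaled to
  the state's RMS gain.
* **Contaminants**: 50 Hz powerline, low-frequency baseline wander, ECG
  bleed-through into the sEMG channels, and wideband noise.

State templates (relaxed/transition/tired): RR mean 0.95/0.76/0.72 s; LF
amplitude 20/30/35 ms; HF amplitude 30/14/12 ms; sEMG gain
0.50/0.62/0.90 mV; spectral center 120/108/85 Hz. Windows are drawn with
Gaussian per-window jitter (RR ±0.05 s, center ±10 Hz, amplitudes ~20–25%
log-scale) so the transition state overlaps both neighbours. The templates
were chosen once so the two modalities are *complementary*: the ECG block
separates the relaxed state sharply (large RR gap) but barely separates
transition from tired, while the sEMG block separates the tired state
sharply but barely separates relaxed from transition. Neither modality
alone resolves all three states; their fusion does — which is exactly the
regime in which feature fusion is worth studying.

What the generator does **not** emulate: real QRS morphology and its
pathologies, respiratory and stochastic HRV, motion artifacts,
electrode-contact drift, subject-level random effects, or nonstationarity
within a window. Passing tests on this generator therefore demonstrate the
correctness and the qualitative behavior of the pipeline, not clinical
performance on real recordings.

## Evaluation

Recognition rate is the fraction of correctly identified test samples,
reported per class and overall. Monte Carlo cross-validation draws
stratified random train/test splits (defaults: 20 repetitions, 30% test);
split indices derive deterministically from one seed, so different models
evaluated with the same seed see *identical* splits and their comparison is
paired. Baselines run on the unfused standardized features: a single-hidden-
layer back-propagation network (16 units, weight decay 5e-4 — `nnet`
provides no early stopping, so decay regularizes instead), k-nearest
neighbours (k = 5, Euclidean, seeded tie-breaking), and linear discriminant
analysis with pooled covariance. `compare_modalities()` evaluates ECG-only,
sEMG-only and fused feature sets over shared splits, all with the IPSO-SVM
by default.

At the desk scale used by the test suite (100 windows per state, 30 s
windows, `q = 50`, `max_iter = 50`, 20 paired splits), the fused model's
mean recognition rate exceeds both single-modality models by a wide margin,
and the per-class pattern matches the physiological expectation: ECG-only
is weakest on transition/tired, sEMG-only weakest on relaxed/transition,
fusion strong everywhere.

## Numerical notes and limitations

* Two printed formulas in the source literature for RMS and median
  frequency are dimensionally inconsistent; the package implements the
  standard definitions matching their verbal descriptions (root mean
  square; the frequency splitting cumulative power in half).
* The fitness landscape over fusion coefficients is a step function (rates
  on a finite validation split), so the swarm's early termination at
  `h_e` can return coarse weights when the validation split is small;
  identification of *which* features matter is reliable when the
  uninformative block dominates the kernel distance (e.g. the 8-feature
  sEMG block replaced by noise) and is not expected when only a small
  block (3 of 11 dimensions) is uninformative — the RBF-SVM is simply
  robust to that.
* The paper-scale swarm (`q = 2000`) and dataset (400 windows per state)
  are supported but not exercised by the default test suite; problem sizes
  in the suite (up to 300 windows, `q <= 50`) were chosen as the smallest
  at which every qualitative property is stable.
* The EMD stage costs ~1.3 s per 60 000-sample channel and is therefore
  switched off (`emd_denoise = FALSE`) in the bulk pipeline configuration;
  the low-pass + notch stages already remove the generator's contaminants
  outside the sEMG band. It remains on by default in
  `preprocess_record()` for single-window use and is fully exercised by
  the test suite.
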