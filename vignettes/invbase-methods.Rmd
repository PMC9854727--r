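---
title: "Inverse-filter baseline removal for subject-independent EEG emotion features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse-filter baseline removal for subject-independent EEG emotion features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invbase)
```

## The problem

EEG amplitude is strongly subject-specific: skull thickness, electrode
impedance and idiosyncratic resting-state rhythms impose, per subject and
channel, a roughly multiplicative gain on the recorded spectrum. Features
extracted from raw trial spectra therefore encode *who* was recorded at
least as strongly as *what they felt*, and a classifier trained on some
subjects transfers poorly to a new one. The usual correction — subtracting
the resting-state (baseline) spectrum from the trial spectrum — removes an
additive offset, but the dominant subject effect is multiplicative, not
additive.

## The model

Treat the recorded trial signal as the emotion-related source degraded by a
subject-specific linear distortion (plus noise assumed removed by upstream
preprocessing). In the frequency domain the degradation is a point-wise
product, so the distortion cancels by point-wise division — inverse
filtering. The resting state is assumed to carry *only* the subject's
baseline character and no emotion content, which makes its magnitude
spectrum an estimate of the distortion itself. The corrected spectrum of a
trial slot is then

    corrected(f) = |trial slot DFT(f)| / |baseline DFT(f)|

computed per channel. Because any per-channel multiplicative gain applied to
a subject's recordings multiplies numerator and denominator alike, the
quotient — and every feature derived from it — is invariant to subject gain.
This package calls the division method `invbase`, the conventional spectral
subtraction `subtractive`, and the no-correction control `nbc`; all three
run behind one interface so they can be compared under identical conditions.

## The pipeline

1. **Slotting** (`segment_slots`): the trial is cut into equal,
   non-overlapping slots (default 6 s); a trailing remainder that does not
   fill a slot is discarded.
2. **Spectra** (`compute_spectrum`): one-sided unnormalised DFT magnitudes
   per channel; phase is discarded.
3. **Baseline removal** (`remove_baseline`): the configured method, applied
   point-wise after the baseline spectrum is linearly interpolated onto the
   slot grid (`align_grids`); the result is restricted to the analysis band,
   default 3–47 Hz.
4. **Windowing** (`window_average`): consecutive slot spectra are averaged
   in groups (default window 12 s = 2 slots); each window is one classifier
   data point.
5. **Band features** (`band_features`): per channel, the mean and population
   variance of the magnitudes in theta (3–7 Hz), alpha (8–13 Hz), beta
   (14–29 Hz) and gamma (30–47 Hz) — 8 values per channel, 256 for a
   32-channel montage, flattened channel-major.
6. **Labels** (`binarize_rating`): 1–9 valence/arousal ratings are split at
   5.5 (the boundary value goes to the high class, so low is exactly
   [1, 5.5)).
7. **Evaluation** (`run_kfold`, `run_loso`): stratified 10-fold
   cross-validation for within-population accuracy, and leave-one-subject-out
   for the subject-independence claim, with accuracy and F1 (positive =
   high class) per unit.

## Numerical choices

* **Magnitude, not power.** Whether spectra are divided as amplitudes or as
  squared magnitudes is form-equivalent for this method (squaring commutes
  with division, and the log-domain equivalence below holds either way);
  the package operates on magnitudes by default and exposes
  `removal_config(spectrum = "power")` as a switch.
* **Division floor.** Division is floored at `epsilon_rel = 1e-8` times the
  channel's maximum baseline magnitude. The inverse-filter model assumes a
  noise-free, strictly positive divisor; the relative floor prevents
  blow-up at near-zero bins without affecting in-band values. A channel
  whose baseline is identically zero passes through undivided, with a
  warning.
* **Grid alignment.** A 6 s slot and a 3 s baseline live on different DFT
  grids (1/6 vs 1/3 Hz spacing). The baseline magnitude is linearly
  interpolated onto the slot grid, with nearest-edge clamping. Zero-padding
  the baseline to the slot length was rejected: it convolves the divisor
  with a Dirichlet kernel and introduces ripple exactly where the division
  is most sensitive.
* **Band edges.** The bands have integer edges (…7 | 8…), which under closed
  intervals would orphan fractional bins such as 7.5 Hz. A bin at frequency
  `f` belongs to band `(lo, hi)` iff `lo <= f < hi + 1`, so the four bands
  tile [3, 48) with no bin lost or double-counted.
* **Variance divisor.** Band variance uses the population divisor (bin
  count): the window spectrum is treated as the complete set of bins, not a
  sample from a larger one.
* **Rating ties.** A rating of exactly 5.5 is classified high.
* **Standardisation.** Features are z-scored with statistics fit on the
  training portion only (fold or training subjects). The band features span
  orders of magnitude and the RBF-SVM and MLP are scale-sensitive; the
  toggle is `classifier_config(standardize = FALSE)`.
* **Classifiers.** The three fixed configurations are an MLP with hidden
  layers (64, 32), an RBF-kernel SVM (`e1071`), and kd-tree kNN with 5
  neighbours (`FNN`). No installed R package provides a two-hidden-layer
  perceptron, so the package includes a compact full-batch Adam-trained
  ReLU/softmax network (`mlp_fit`), deterministic given its seed; its
  training regime (300 epochs, learning rate 1e-2, L2 1e-4) is recorded in
  every report's config snapshot.

## What the synthetic generator emulates

Real affective-EEG corpora are access-restricted, so the package ships a
generator whose trials obey the degradation model the method targets,
with a DEAP-like geometry: 32 subjects × 40 trials, 32 channels at 128 Hz,
60 s trials, 3 s baselines, ratings on 1–9.

* **Emotion signal**: band-limited complex white noise whose per-band power
  follows the class effects; by default the low class carries 1.5× power in
  theta and alpha and the high class 1.5× in beta and gamma. Band-limited
  noise (rather than sinusoids) keeps the band mean/variance features
  genuinely distributional.
* **Subject kernel**: a strictly positive, spectrally smooth per-channel
  gain (Gaussian log-gain at 5 Hz knots, spline-interpolated,
  exponentiated) with across-subject log sd `subject_gain_sd = 1.0` —
  subjects differ by typical gain factors of ~e, in line with the
  order-of-magnitude spread of absolute band power across people. Within a
  subject, channel log-gains correlate at `channel_gain_cor = 0.8`: a
  subject's gain is mostly a global amplitude property (skull, impedance)
  with smaller channel-specific deviations. This correlation matters: were
  channel gains independent, averaging evidence over channels would cancel
  the subject confound and even uncorrected features would transfer across
  subjects, which is not what real recordings show.
* **Class-effect magnitude**: 1.5× band power is clearly detectable within
  subject (within-subject k-fold accuracy is near ceiling) yet subordinate
  to the sd = 1.0 subject spread, reproducing the regime reported on real
  data where uncorrected features transfer across subjects at roughly
  chance level while inverse-filtered features transfer well.
* **Trial synthesis**: the trial spectrum is the emotion spectrum times the
  kernel, inverse-transformed with random phase; the baseline is the kernel
  under a flat unit-magnitude excitation with independent random phase, so
  its magnitude spectrum equals the kernel exactly at zero noise. Using an
  independent excitation (not the trial's own distortion realisation) keeps
  the divisor statistically rather than numerically equal to the trial's
  distortion, which exercises the interpolation and the floor honestly.
  White sensor noise (`noise_sd = 0.05` of the ~unit signal scale) is added
  to both signals.
* **Ratings** are 2.5/7.5 so labels pass through the ordinary 5.5
  binarization rather than bypassing it.

What the generator does *not* emulate: 1/f background shape, artifacts
(EOG/EMG), electrode geometry and cross-channel correlation of the signal
itself, non-stationarity within a trial, and rating ambiguity near the
threshold. Passing tests on this generator therefore demonstrate that the
pipeline removes multiplicative subject distortion under its own model
assumptions — not that any particular accuracy will be attained on real
recordings.

## Evaluation design

Stratified folds preserve class ratios (the protocol spec for the k-fold
experiments does not state stratification; it is the default here and a
seed-controlled one). Windows of the same trial may fall into different
folds under k-fold — the window, not the trial, is the data point — while
leave-one-subject-out never splits a subject by construction. Multiclass
input (e.g. a 62-channel, 3-class layout) reuses the same machinery with
macro-averaged F1.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run a scaled-down study — 8
subjects × 20 trials on 8 channels, three replicate simulations — chosen so
the complete suite runs comfortably on a laptop while the leave-one-subject-out
contrast (inverse filtering high, no-correction near chance) remains
unambiguous. The full DEAP-shaped geometry (32 × 40 × 32 channels) is
exercised for generation and feature-shape contracts.

## Known limitations

* The inverse-filter divisor is a single 3 s baseline spectrum — a noisy
  estimate in real data; no smoothing or shrinkage of the divisor is
  applied (and none is specified by the method).
* Whether the original method divides complex spectra or magnitudes, and
  how it matches slot and baseline grids of different lengths, is
  under-specified; this implementation divides magnitudes on the
  interpolated grid and documents both choices prominently.
* The EDF reader supports one continuous uniform-rate recording per file
  (16-bit EDF); EDF+ annotations, discontinuous records and multi-trial
  concatenation are out of scope.
* No feature selection, per-subject normalisation layers, or deep baselines
  are included; the point of the package is the correction step, evaluated
  with deliberately simple features and classifiers.

## A worked example

```{r example, eval = FALSE}
library(invbase)
library(dplyr)

cfg <- synth_config(n_subjects = 8, n_trials_per_subject = 20,
                    n_channels = 8, subject_gain_sd = 1.0, seed = 0)
ds <- generate_dataset(cfg)

reports <- lapply(
  c(invbase = "invbase", subtractive = "subtractive", nbc = "nbc"),
  function(m) {
    ds |>
      assemble_features(removal_config(m), slot_seconds = 6,
                        window_seconds = 12) |>
      run_loso("valence", classifier_config("mlp", seed = 0))
  }
)
bind_rows(lapply(reports, glance), .id = "method")
plot_method_comparison(reports)
```
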