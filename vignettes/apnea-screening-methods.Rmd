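---
title: "Screening sleep apnea from single-lead ECG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening sleep apnea from single-lead ECG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ApneaScreenR)
```

## The screening problem

Sleep apnea syndrome (SAS) is diagnosed by overnight polysomnography, which
is burdensome and scarce. Repetitive apneas and hypopneas leave a readable
trace in the electrocardiogram: a slow cyclic bradycardia–tachycardia
oscillation of the RR-interval series (cyclical variation of heart rate,
CVHR, well below 0.04 Hz) and a concomitant slow modulation of the R-peak
amplitude driven by respiratory effort and thoracic impedance. Normal sleep
instead shows respiratory sinus arrhythmia (RSA) in the high-frequency band
(0.15–0.4 Hz). A single-lead ECG therefore suffices, in principle, to
classify each one-minute segment of a night as apneic or normal, to
accumulate those calls into an apnea–hypopnea index
(AHI = 60/T × number of apneic minutes, with T the annotated recording time
in minutes), and to screen for SAS at the clinical threshold AHI ≥ 5.

The package implements that pipeline end to end, with one methodological
addition: the per-minute classifier does not see one minute at a time.
Because apnea is a continuous phenomenon whose cardiac response develops
after event onset and persists for minutes after the event ends, the feature
vector for a target minute *t* is the concatenation of the per-minute
features for minutes *t − past … t … t + future*. The (past, future) pair is
a tunable window; (0, 0) is the non-time window, and `gridSearchWindows()`
scans the 0–15 × 0–15 grid for the accuracy-maximizing pair.

## Pipeline stages and their parameters

**Preprocessing.** A windowed-sinc (Hamming) linear-phase FIR bandpass with
cutoffs 3 and 45 Hz removes baseline wander and mains hum while keeping the
QRS complex. The tap count defaults to the next odd integer at or above the
sampling rate (~1 s impulse response), which gives better than 20 dB
rejection at 0.3 Hz and 50 Hz for 100 Hz recordings. The filter is applied
forward with exact group-delay compensation, so it is zero-phase and
length-preserving; edges are handled by signal reflection.

**R-peak detection** follows the Hamilton scheme: differentiate, rectify,
integrate over an 80 ms moving window, then accept integrated-signal peaks
against an adaptive threshold placed between running averages of recent QRS
and noise peaks (coefficient 0.3125), with a 200 ms refractory period and a
search-back pass that rescues beats in gaps longer than 1.5× the running
mean RR at half threshold. Detections are localized to the filtered-signal
maximum within ±100 ms, and the R amplitude is read from the filtered
signal there — detection operates on the filtered signal, and raw
amplitudes would be contaminated by baseline wander. All constants are
exposed as arguments with these defaults.

**RR cleaning.** Physiologically uninterpretable intervals (outside
300–2000 ms by default) are replaced by the median of a 5-beat window
centered on the suspect interval; in-band intervals pass through untouched.
This conditional median filter targets outliers rather than smoothing the
series. Edge windows shrink symmetrically, and a replacement median that is
itself out of band is clamped to the nearest bound, which makes the
operation idempotent. A series that is entirely out of band is an error
rather than a fabricated signal.

**Features.** Each annotated minute yields 18 features: six time-domain RR
features (MRR, MHR as the mean of the per-beat instantaneous rate, RMSSD,
SDNN, NN50, pNN50 with the number of RR intervals as divisor), six RR
spectral features and six R-amplitude spectral features (VLF 0–0.04 Hz,
LF 0.04–0.15 Hz, HF 0.15–0.4 Hz as half-open bands, plus LF/HF, LF/(LF+HF),
HF/(LF+HF)). SDNN uses the population (divide-by-N) form by default, with a
flag for the sample form. RR intervals are assigned to the minute containing
their terminating R peak.

Spectra are estimated by cubic interpolation of the beat-indexed series onto
a uniform 3 Hz grid over the segment, mean removal, Hamming windowing and an
FFT of length 256. A one-minute segment at 3 Hz yields fewer samples than
the FFT length, so the Welch estimate degenerates to a single zero-padded
modified periodogram — deterministic, which keeps every downstream result
exactly reproducible; longer inputs fall back to averaged 50 %-overlap
segments. Band power is the PSD integral over each half-open band. When
LF + HF is zero (a constant segment), the three ratios are defined as 0
rather than dividing by zero. The amplitude-family ratios mirror the RR
ratios as LF/(LF+HF) and HF/(LF+HF); an alternative literal convention
LF/(LF/HF), HF/(LF/HF) is selectable via `ratioConvention = "literal"` for
comparability, but since LF/(LF/HF) is algebraically HF we treat the sum
convention as the intended reading.

Minutes with fewer than 10 beats, or whose beat series spans less than 30 s,
cannot support spectral estimation; they are marked invalid and carry NA
features. At classification time invalid segments are imputed with the
training-partition per-feature mean (exactly 0 after z-scoring), keeping the
per-minute grid intact so the AHI denominator remains the full annotated
time; the `valid` flag is retained for audit.

**Normalization** is a z-score with mean and population SD fitted on the
training partition only and applied unchanged to validation/test rows, so no
statistic leaks across the subject split. Constant features get scale 1.
Normalization statistics are refitted inside every cross-validation fold.

**Windowing.** For each target minute the per-minute vectors for
*t − past … t + future* are concatenated in temporal order
(18 × (past + future + 1) columns). Context never crosses a recording
boundary. Out-of-range context minutes replicate the nearest existing
minute's vector by default, so every annotated minute remains a classifiable
row — necessary because AHI divides by total annotated time; zero-fill and
drop policies are selectable. Grid-search ties are broken toward the
smallest past + future, then the smallest future: the cheapest context wins.

**Classifiers.** Five reference classifiers sit behind one train/predict
contract with fixed published hyperparameters: a multilayer perceptron
(hidden layer of 2·p + 1 units computed from the actual windowed feature
count p, L2 penalty alpha = 1, at most 1000 epochs), an RBF-kernel SVM
(C = 9.9, tolerance 5 × 10⁻⁴, probability-calibrated scores), a random
forest (148 trees, depth cap 185, 15 candidate features per split capped at
the feature count, seed 42), gradient-boosted trees (eta 0.1, up to 10000
rounds with early stopping after 50 stagnant rounds on a seed-fixed grouped
10 % holdout of the training rows, depth 9, min_child_weight 0.121,
gamma 6.45 × 10⁻⁷, colsample_bytree 0.876, subsample 0.872) and logistic
regression. SVM, RF, XGBoost and LR delegate to e1071, ranger, xgboost and
`glm.fit`; unlisted settings stay at those libraries' defaults and every
value actually used is recorded in the experiment run log.

The MLP is implemented in the package as a single-hidden-layer network
(ReLU hidden layer, logistic output) trained by minibatch Adam
(learning rate 10⁻³, batch 200, shuffled each epoch, stopping early when the
epoch loss improves by less than 10⁻⁴ for 10 consecutive epochs), with the
L2 penalty applied per batch. This mirrors the reference semantics the
printed hyperparameter names come from, is deterministic given the seed,
and — because every heavy step is a BLAS matrix product — fits networks with
tens of thousands of weights in seconds, which quasi-Newton full-batch
trainers cannot do at the problem sizes the windowed design matrices reach.

**Evaluation.** Grouped k-fold cross-validation shuffles the record ids with
a seeded RNG and deals them round-robin into folds, so all segments of a
recording stay on one side of every split (with 35 records this reproduces
the 28/7 protocol). Per-segment metrics are accuracy, sensitivity,
specificity, precision, F1 and AUC; AUC is the midrank Mann–Whitney rank
statistic over the continuous scores, so tied scores are handled by the
midrank convention. Per-recording evaluation converts per-minute detections
into AHI with T equal to the number of annotated minutes (the same grid the
classifier scores), screens at AHI ≥ 5 (boundary positive), and reports the
SAS confusion metrics plus Pearson's r between predicted and actual AHI.
Train/test record overlap is rejected at every entry point.

## What the synthetic data emulate

`generateDataset()` draws labeled recordings whose per-minute labels form
alternating normal/apneic episodes (uniform lengths, defaults 3–10 and 2–6
minutes, apneic fraction constrained to 0.1–0.7). With
`healthyFraction > 0` the generator instead emulates a screening cohort:
that fraction of recordings are non-SAS controls carrying at most four
isolated apneic minutes (AHI < 5), interleaved deterministically (every
`1/healthyFraction`-th record) so any contiguous train/test split contains
both recording classes — necessary for the per-recording SAS specificity
that real screening cohorts measure, since an all-apneic cohort has no
negatives at the recording level. The instantaneous RR is

- a per-record baseline (850 ms ± 40 ms between records),
- a Mayer-wave-like LF oscillation (25 ms at 0.095 Hz) in every minute,
- RSA at 0.25 Hz in every minute — fuller in normal minutes (×0.5–1.5),
  reduced but present in apneic ones (×0.2–0.8), since obstructive events
  retain respiratory effort,
- the apneic CVHR oscillation (70 ms at 0.025 Hz) scaled by a per-minute
  expression strength uniform in [0.1, 1.9],
- non-apneic VLF activity in normal minutes (half-normal amplitude,
  SD 50 ms, at 0.02 Hz), standing in for sleep-stage drifts and arousals,
- white per-beat jitter (30 ms), with all RR clipped to 400–1800 ms.

Two temporal mechanisms make the study conditions genuinely windowed: the
cyclic response builds up after episode onset (the first minute of each
apneic run expresses at half strength) and persists after the episode ends
(carry-over factors 0.6/0.35/0.15 over the following minutes, applied to
minutes labeled normal). R-amplitude factors mirror the same structure:
apneic modulation depth 0.15 × strength at the CVHR frequency, normal-minute
slow drift (half-normal, SD 0.18) plus respiratory modulation (0.08), and
white amplitude jitter (0.05). The ECG itself is a PQRST-like sum of
Gaussian bumps (dominant R bump ≈ 20 ms wide) placed at the cumulative beat
times, plus baseline wander (0.3 Hz), mains hum (50 Hz) and broadband noise,
sampled at 100 Hz and 16-bit-quantizable.

These defaults were fixed while designing the generator so that the
resulting task sits in a realistic regime — per-segment accuracy for the
unwindowed random forest near 0.9 rather than at ceiling, classes
overlapping through shared VLF/LF power and shared amplitude drift, and
boundary minutes (onsets, post-episode carry-over) that a single minute's
features cannot resolve but temporal context can. They are study conditions,
not tuning knobs, and the test suite runs against them unchanged.

What the generator does *not* emulate: realistic PQRST morphology and its
inter-subject variability, ectopy and arrhythmia (an optional
`ectopicRate` plants out-of-band RR spikes only to exercise the median
filter), sleep-stage architecture, apnea-type differences (central versus
obstructive), movement artifacts, and electrode pop. Passing tests on these
data therefore demonstrate that the pipeline is implemented correctly and
that the windowing mechanism extracts real temporal information — not that
the specific accuracy numbers transfer to clinical recordings. Reproducing
the published clinical-data protocol requires the public Apnea-ECG
recordings; the package reads their WFDB dialect, and `runExperiment()`
with `split = "train_test"` implements the released/withheld protocol
unchanged.

## Numerical and design choices

- Problem sizes in the tests and the acceptance script are 30 recordings of
  60 annotated minutes (20 train / 10 test), with 10 replicate seeds for
  the windowing-benefit check; these sizes keep the full suite fast on one
  CPU while leaving ~600 test segments per replicate, enough to resolve
  accuracy differences of one segment in six hundred.
- Fold assignment, per-record generator seeds (derived from the master seed
  with a fixed hash) and every classifier seed are explicit, so every
  artifact — serialized datasets, feature tables, experiment reports — is
  byte-identical across reruns with the same seed.
- Feature tables are written with 17 significant digits (lossless for
  doubles); the WFDB signal dialect quantizes to 16-bit at gain 200, so a
  signal round-trip is exact to half a quantization step.
- The annotation reader rejects recordings whose annotation count differs
  from the floor of the signal duration by more than one minute instead of
  guessing an alignment; a trailing partial minute without annotation is
  dropped from the segment grid.
- Records with a single annotated class, folds missing a class, empty
  training partitions and single-class AUC all raise errors naming the
  problem rather than returning silent NaNs.

## Known limitations

- The RF `max_features = 15` setting exceeds the 18-feature unwindowed
  input's sensible range only marginally, but is applied literally (capped
  at the feature count where smaller), as printed.
- The MLP trainer is a faithful but minimal Adam implementation: no
  learning-rate schedules, no validation-based early stopping.
- The Welch estimator's single-segment degeneration at one-minute inputs
  means VLF estimates lean on spectral leakage through the Hamming window's
  main lobe; this is shared by target and context minutes alike and is the
  standard compromise at this segment length.
- AHI severity strata (5/15/30) and cross-classifier statistical
  comparisons are out of scope; the screening decision is the binary
  AHI ≥ 5 call.
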