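---
title: "Beat score maps: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat score maps: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

ECG rhythm diagnosis differs from beat diagnosis in that the unit of
classification is a *sequence*: the same normal-looking beats, differently
spaced or interleaved with ectopic beats, constitute different rhythms.
`bsmecg` encodes a 10-second single-lead window as a **beat score map**
(BSM), an image with time on one axis and the 15 MIT-BIH beat classes on
the other:

- each annotated beat contributes its classifier **score vector** (the full
  softmax over beat classes, not the argmax), placed at the time index of
  its R peak;
- all other time points are zero, so the lengths of the zero runs encode
  the R–R intervals ("interval padding");
- the 3600 × 15 matrix (10 s × 360 Hz) is reduced one-tenth along time and
  the class axis is replicated tenfold, giving a 360 × 150 image for a 2-D
  convolutional classifier.

The representation therefore carries, in one object, the three classical
rhythm discriminators: beat identity (which class bands light up), beat
pattern (the order of bands along time), and R–R structure (band spacing
and its regularity). Soft scores rather than hard labels preserve graded
information — an ambiguous beat contributes an ambiguous column.

Assumptions: R-peak positions and beat labels are given (database
annotations or a trained beat classifier; the package does not detect
peaks); a window carries a single rhythm label (windows spanning rhythm
boundaries without a strict majority are dropped); the sampling rate is
constant within a record.

## Processing stages and their parameters

### Denoising (whole records, before windowing)

| parameter | default | meaning |
|---|---|---|
| `wavelet` | `"db4"` | Daubechies-4 (8 taps, 4 vanishing moments) |
| `baseline_level` | 9 | drift band ≈ 0–0.35 Hz at 360 Hz |
| `highfreq_level` | 6 | analysis depth for the noise filter |
| `cut_hz` | 45 | lowest suppressed frequency |

Baseline wander is removed by zeroing the deepest approximation of a
level-9 decomposition: at 360 Hz that band is ≈ 0–0.35 Hz, below the
slowest rhythm content of interest. High-frequency noise is removed by
zeroing detail bands. A nominal 45 Hz cut-off would zero only the two
finest bands (45–90, 90–180 Hz), but db4's band edges are soft: a
mains-frequency (50/60 Hz) tone leaks substantially into the nominally
22.5–45 Hz band and would survive. The filter therefore zeroes every
detail band whose *upper* edge reaches the cut — the three finest at
360 Hz. The price is partial loss of the 22.5–45 Hz QRS energy; the
per-beat scalograms still separate beat classes well (see the test suite),
and a sharper cut would require a longer wavelet than the method specifies.

Numerically, the pyramid uses periodized filtering on a symmetric
extension of the signal to the next multiple of 2^depth, which makes the
transform exactly invertible; zeroed-band reconstruction is an orthogonal
projection and hence idempotent (exactly so whenever 2^depth divides the
signal length, as for all 10-s windows at 360 Hz). The high-frequency
filter only decomposes as deep as the deepest zeroed band — deeper analysis
would reconstruct unchanged bands identically and only add padding error.
Denoising is applied to whole records rather than windows to avoid
per-window edge artefacts.

### Windowing

`window_s = 10` s, `stride_s = 1` s; window starts at 0, 1, 2, … s while a
full window fits. The label rule (`label_rule = "majority"`) assigns the
label of the rhythm region covering more than half the window and drops the
window otherwise. The rule at rhythm boundaries is a design decision: one
label per window is recorded, a strict majority is the least arbitrary
tie-break, and an exact 50/50 split yields no label rather than a coin
flip.

### Beat chunks and scalograms

Chunks span `chunk_s = 2.4` s centred on the R peak (864 samples at
360 Hz), zero-padded at record edges; they are cut from the *record*, so
beats near a window boundary keep their real context. Scalograms use an
analytic Morlet mother wavelet (`omega0 = 6`) on `n_scales = 32`
logarithmically spaced frequencies between `fmin_hz = 0.5` and
`fmax_hz = 50` — the band where P/QRS/T morphology lives. The magnitude
image is min–max scaled to [0, 1] per chunk before classification, a
standard normalization for image backbones. A pure tone peaks at the grid
frequency nearest its own (within one logarithmic grid step for short
chunks), which the tests verify at 2, 5, 10 and 25 Hz.

### BSM construction

Reduction uses a per-class **block max** over each 10-sample block. Naive
decimation would drop a single-column beat with probability 0.9; block max
preserves every beat's scores, and two beats sharing one 27.8-ms block
(physiologically impossible for genuine R peaks) merge to the elementwise
max. Resizing replicates each class column 10× (nearest neighbour);
interpolation would blur score values across class bands and destroy the
score semantics. Matrices carry a `stage` attribute (`raw` → `reduced` →
`resized`), and re-applying a stage is an error, never silent
reprocessing. Images persist as 16-bit grayscale PNG
(`round(score * 65535)`) with a JSON sidecar holding the label, provenance
and the beat-vocabulary order; the vocabulary *order* defines the class
axis and is stored with every trained model.

### Classifiers and training

Both classifiers share a compact architecture: fixed average-pooling of
the input, one convolution (time-axis kernel spanning the full class/scale
axis), ReLU, max-pooling along time, a hidden dense ReLU layer, and a
softmax output, trained with Adam on cross-entropy. Defaults
(`training_config()`): learning rate 0.001, 30 epochs, batch size 16,
5 folds, 8 filters, hidden width 32, temporal kernel 25 rows. The source
study reports batch size 16 in one section and 4 in another; 16 is the
default and 4 remains reachable through the config. The temporal kernel is
sized so the receptive field covers at least two consecutive R peaks even
in bradycardia (25 rows ≈ 1.4 s at the pooled resolution) — a filter that
never sees two beats cannot measure an interval, and with shorter kernels
the rhythm classes that differ only in R–R structure are systematically
confused.

Class imbalance is handled by weighted random sampling: each window is
drawn with probability proportional to 1/(count of its class), so the
expected class composition of every mini-batch is uniform. Cross-validation
stratifies folds at the window level; windows of one record may land in
different folds (the source does not state whether its folds separate
records, and with overlapping 1-s-stride windows an intra-record split
inflates absolute numbers — a caveat for interpreting any benchmark, not a
correctness issue for the machinery).

The `vgg16-transfer` backbone mirrors the transfer-learning contract
(pretrained initialisation, all layers fine-tuned) but requires externally
supplied weights; the package ships none, so calling it without them is an
informative error, and all bundled experiments use `small-cnn`.

## Metrics

`per_class_metrics()` computes one-vs-rest Sen = TP/(TP+FN),
Pre = TP/(TP+FP), Spec = TN/(TN+FP), per-class Acc = (TP+TN)/total,
F1 = harmonic mean of Pre and Sen, and overall accuracy = trace/total,
reported as percentages rounded half-up to two decimals (raw ratios are
kept in an attribute). Conventions: a never-predicted class has F1 = 0
with a warning; a class with no true instances has undefined (missing)
sensitivity, not 0. The published per-class tables shipped for reference
reproduce exactly from the published confusion matrices for Sen, Pre, F1
and Acc — but **not** for the specificity column (e.g. the 5-class N row
computes to 99.51 against a printed 99.45); the published specificity
definition is evidently not one-vs-rest on the pooled matrix (possibly a
per-fold average), so specificity is computed by the standard formula and
excluded from reproduction checks. Similarly, the published 6-class sample
table lists 549 AFL windows while the published confusion matrix's AFL row
sums to 546; the confusion matrix is taken as authoritative.

## The synthetic generator: what it does and does not emulate

`generate_record()` renders each beat symbol as a distinct Gaussian-mixture
QRS-like template (varying QRS width, Q/S asymmetry, R amplitude, T wave;
maximum exactly at the annotated sample) and draws R–R intervals from a
log-normal process with the spec's mean and coefficient of variation.
Default class specifications (`default_rhythm_specs()`): N 0.80 s CV 0.05;
AFIB 0.75 s CV 0.25 (irregularly irregular, flat baseline); AFL 0.60 s CV
0.04 plus a 5 Hz (300/min) sawtooth flutter baseline of 0.15 mV; SVTA
0.35 s; B alternating N/V; T the N/N/V triplet; SBR 1.20 s; P a 0.85 s
paced rhythm of paced beats. A 0.05 mV, 0.25 Hz sinusoidal drift is added
record-wide, and `add_noise()` injects white Gaussian noise calibrated so
the *realized* SNR equals the requested dB value exactly.

This emulates the structure the method exploits — beat identity, beat
pattern, R–R statistics, drift, a flutter-like baseline — but not
physiological morphology: no realistic P waves, no fibrillatory f-waves,
no inter-patient template variability, no annotation errors. Passing tests
therefore demonstrate that the machinery recovers class structure that is
present by construction; they say nothing about accuracy on real ECG,
which depends on morphological subtleties the generator does not model.

One consequence is visible in the noise experiment: with white noise,
wavelet denoising removes most injected power (everything above ≈22.5 Hz),
annotated R positions are unaffected by noise by design, and the synthetic
templates remain separable after denoising down to −6 dB, so rhythm
performance is essentially flat across clean / 6 dB / −6 dB (the
degradation ordering holds, largely with equalities) — whereas on real
data the −6 dB condition degrades genuinely ambiguous morphology. The
acceptance experiment asserts the non-strict ordering, which is what the
synthetic conditions support.

## Problem sizes used by the bundled experiments

The test-suite and acceptance-script experiments use: 200 windows per
class for the six-class end-to-end study (one 209-s single-rhythm record
per class, 1-s stride), 150 + 50 chunks per class for beat-classifier
checks, 1000 random windows for the BSM invariants, and the same six-class
set for the noise experiment. These sizes give stable statistics at
desk scale while keeping a full run in minutes on one CPU.

## Known limitations

- R-peak *detection* is out of scope; annotation quality bounds BSM
  quality.
- Benchmarks against the MIT-BIH database require the external database
  and full-scale training; the package ships the machinery and the
  published reference tables, not retrained weights.
- The native WFDB reader covers headers, format 212/16 signals and
  MIT-format annotations (including rhythm aux markers) — the subset the
  MIT-BIH arrhythmia records use — not the full format zoo.
- `small-cnn` is deliberately compact; it is the deterministic, dependency-
  free default, not a claim that it matches a fine-tuned VGG16 on real
  data.
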