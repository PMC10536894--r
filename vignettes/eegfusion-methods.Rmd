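---
title: "Methods: multi-branch convolutional decoding of motor-imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-branch convolutional decoding of motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Motor imagery — mentally rehearsing a hand or foot movement without
executing it — modulates sensorimotor EEG rhythms: the mu (8–12 Hz) and
beta rhythms over motor cortex *desynchronize* (lose band power)
contralaterally to the imagined limb. Brain–computer interfaces decode
these modulations into commands. Decoding across subjects is hard because
the spatial and spectral expression of the rhythms is highly
individualized; a single fixed filter bank that is optimal for one person
is suboptimal for another.

`eegfusion` implements a multi-branch convolutional answer to that
problem: five parallel EEGNet-style branches, each with a different
temporal kernel length (and so a different spectral resolution), whose
flattened feature maps are concatenated in a fusion layer before a softmax
head. A branch that suits one subject's rhythms can dominate the fused
representation for that subject's data while other branches carry others.

## Model

Each branch receives the identical `(C, W)` input (C channels, W samples)
and applies, in order:

1. **Temporal convolution** — `F1` kernels of shape `(1, k)`,
   length-preserving ("same") padding, no bias: a learned frequency
   filter bank. Batch normalization follows.
2. **Depthwise spatial convolution** — kernels of shape `(C, 1)` with
   depth multiplier `D`, collapsing the channel axis: per-temporal-filter
   spatial patterns (the network's analogue of common spatial patterns).
   Each `(C)`-vector is constrained to max-norm 1.0. Batch normalization,
   ELU, average pooling `(1, 4)`, dropout 0.5.
3. **Separable convolution** — a depthwise temporal convolution of shape
   `(1, ks)` followed by a pointwise `1×1` convolution to `F2` maps,
   summarizing each feature map over time and then mixing maps. Batch
   normalization, ELU, average pooling `(1, 8)`, dropout 0.5.

The five branches use `F1 = 8, 16, 32, 64, 128`,
`k = 64, 80, 96, 112, 128`, `F2 = 16, 32, 64, 128, 256` and
`ks = 8, 16, 32, 64, 128` (`default_v2_spec()`); `test_config_spec(1..5)`
exposes the published filter-size ablations, which vary only `k`.
Flattened branch outputs are concatenated (the *fusion layer*) and a dense
layer with bias feeds a softmax over the classes.

The depth multiplier (2) and the pooling lengths (4, 8) are not stated for
this architecture in its published description; they are the EEGNet
defaults, and every one of them is a `branch_spec()` field, so any other
choice is a configuration rather than a code change. The same applies to
the fusion head, where we include a bias and no norm constraint.

## Training protocol

`eegnet_fusion()` optimizes with Adam (default learning rate `1e-5`, the
published value), binary cross-entropy through the softmax for two-class
problems and categorical cross-entropy otherwise — the published protocol
states binary cross-entropy globally, which is not well defined for four
mutually exclusive classes, so the four-class case deviates deliberately
(both losses are available via `train_config(loss = )`).

Data are split 70/10/20 into train/validation/test by a seed-determined
uniform permutation (`split_dataset()`; floor-based sizes, remainder to
train). Session-structured recordings use `session_split()` instead, with
a validation carve-out from the training sessions. After every epoch the
validation accuracy is computed; the weights of the best epoch (first
occurrence on ties) are checkpointed and restored into the returned model.
Batch size (16) and epoch count (100) are unstated in the source protocol
and configurable.

Every stochastic component — the split, Glorot-uniform initialization,
shuffling, dropout masks — draws from one seeded RNG scope
(`train_config(seed = )`), so a fit is a pure function of data, spec and
control. The RNG state of the calling session is left untouched.

## The synthetic world

`simulate_recording()` generates the *stated world* all tests run in:

* geometry defaults follow the PhysioNet motor-imagery corpus at desk
  scale — 160 Hz, 4 s trials, 45 trials per recording, labels `T1`/`T2`;
* 8 channels by default rather than 64: enough for contiguous left/right
  channel blocks while keeping every test CPU-cheap (channel count never
  enters any geometry assertion);
* background = 1/f-shaped noise (unit variance) + white noise
  (`noise_std`, default 1 µV): an EEG-like spectrum without modeling
  physiology;
* a sinusoidal rhythm in `erd_band_hz` (default 8–12 Hz, the mu band) of
  amplitude `rhythm_amp` (default 2 µV, a realistic rhythm-to-noise
  ratio), frequency and phase randomized per trial segment so no phase or
  exact-frequency cue is learnable;
* class *k* attenuates the rhythm by `erd_depth` on the *k*-th contiguous
  channel block during its trials — the event-related desynchronization
  carrying the class information; `erd_depth = 0` is the null world;
* 1 s unannotated inter-trial gaps (real rest periods are longer; the gap
  only has to separate trials, and shorter gaps keep records compact).

What the generator does **not** emulate: volume conduction and realistic
spatial mixing, ocular/muscular artifacts, non-stationary drifts,
inter-subject variability. A green learnability test therefore establishes
that the architecture, gradients and training loop can extract a
lateralized band-power contrast end-to-end — not that the published
real-data accuracies are reproduced. Those require the three public
corpora and GPU-scale training, and are out of scope by design.

## Preprocessing recipes

* `eegmmidb`: 60 Hz notch (Q = 30; only the frequency is published, Q is
  our documented default) then Butterworth band-pass 2–60 Hz of order 5,
  both zero-phase (forward–backward) on the *continuous* recording so
  filter transients and group delay never land inside an 80-sample
  window; 4 s epochs from the annotation onset (offset unstated in the
  source; 0 assumed); rest annotations excluded by `keep_labels`; eight
  non-overlapping 80-sample windows per epoch, stride equal to length —
  the "sliding window" of the protocol is a partition, and each window
  inherits its epoch's label.
* `bci2a` / `bci2b`: 4.5 s epochs offset 1.5 s after the cue (1125
  samples at 250 Hz), no re-filtering beyond the corpora's native
  0.5–100 Hz acquisition band, per-channel z-scoring with training-set
  statistics (`standardize()`); EOG channels are never model input.

Coordinates are 0-based samples with half-open `[onset, onset + dur)`
intervals; trailing partial windows and epochs are dropped, never padded.

## Numerical choices

* Butterworth design by analog prototype → band transform → bilinear
  transform; coefficients agree with the scipy reference design to
  1e-12 (frozen in the test suite). `filtfilt` uses odd-reflection
  padding of length `3 * (n_taps - 1)` and steady-state initial
  conditions, matching the scipy defaults.
* Filter attenuation is asserted on the steady-state core of a test tone
  (1 s trimmed per edge): the zero-phase edge transient otherwise
  dominates an RMS measurement of a >60 dB notch.
* Batch normalization uses eps 1e-3 and running-stat momentum 0.99 (Keras
  defaults). With very few optimizer steps the running statistics lag the
  batch statistics and inference-mode accuracy trails train-mode
  accuracy; tests on tiny fixtures therefore use small batches (more
  updates per epoch). This is a property of the convention, not a bug.
* Convolutions use TF-style "same" padding (extra sample on the right for
  even kernels). Average pooling floor-divides and drops the remainder
  (with `W = 80`, pooling 4 then 8 gives `20 -> 2` steps, discarding 4).
* Softmax probabilities are clipped to `[1e-7, 1 - 1e-7]` inside the
  losses; argmax ties break toward the lowest class index.
* Precision/recall/F1 are 0 (with a warning) when their denominator is 0.
* Backpropagation is hand-written and verified against central-difference
  numerical gradients (tolerance `1e-6 + 1e-4 |g|`) for every parameter
  group under both losses.

## Design decisions that were genuinely open

* **Null-world control.** Window-level random splitting places windows of
  the same trial in both train and test. Windows of one trial share
  slow-noise context, so a memorizing network gains above-chance test
  accuracy *with no class signal at all* — leakage inherent to the
  published split protocol, not a generator artifact. The no-ERD control
  therefore holds out whole trials (one window per trial), which is the
  clean statement of "nothing to learn"; the leakage effect itself is
  real and documented here.
* **Learnability at CPU scale.** The published training (lr 1e-5, many
  epochs, GPU) is emulated by a raised learning rate (1e-3) and few
  epochs. The model spec is untouched; only optimization length changes.
* **EDF+ subset.** The writer emits EDF+C with 1 s records (or one record
  for fractional-second recordings), 16-bit quantization over a
  power-of-ten physical range, and annotations as standard TALs. It
  round-trips everything this package produces; it is not a
  general-purpose EDF library.
* **JSON configuration** for `run_pipeline()`: human-readable, diffable,
  nested sections mirror the constructor arguments, no extra dependency.

## Known limitations

* No artifact rejection, channel interpolation or re-referencing; the
  recipes assume clean(ed) input.
* The BCI IV-2a/2b recipes are exercised on synthetic geometry only; GDF
  reading is out of scope (EDF+ and the delimited sidecar format are the
  ingestion paths).
* Training is single-threaded CPU R/BLAS; it is meant for desk-scale
  experiments and tests, not for reproducing GPU-scale benchmarks.
* Inference timing is reported informationally and never asserted: it is
  hardware-dependent.
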