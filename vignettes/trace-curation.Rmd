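---
title: "Deep-learning curation of single-molecule fluorescence traces"
author: "smTraceNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning curation of single-molecule fluorescence traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-molecule fluorescence microscopy produces one intensity-versus-time
trace per candidate molecule: a single channel for kinetic-fingerprinting
assays (repeated probe binding to a surface-immobilized target produces an
on/off "telegraph" signal), or a donor/acceptor channel pair for smFRET,
where anticorrelated intensity changes report conformational dynamics.
Before any kinetic or FRET analysis, traces must be curated: photophysical
artifacts (photobleaching, multi-state junk, non-anticorrelated channels,
low signal-to-noise) must be screened out, and for smFRET only the segment
of each trace preceding the first photobleaching event is analyzable.
Manual curation is slow and subjective; this package automates it with
recurrent and convolutional classifiers, and supplies a Monte-Carlo trace
simulator so that the entire pipeline is trainable and testable without any
experimental data.

## Model families

All four networks are small, fixed templates built by `networkSpec()`:

* **`simreps_lstm`** (5 layers) — one-channel classifier: binned sequence
  input, one bidirectional LSTM (sequence-to-one), dropout, dense,
  2-way softmax. The output score in [0, 1] is the probability that a trace
  shows mutant-like repeated binding (`MUT`) rather than wild-type-like or
  background behaviour (`WT`).
* **`fret_classifier_lstm`** (7 layers) — two-channel Accept/Reject
  classifier with a second bidirectional LSTM stage.
* **`fret_segmenter_lstm`** (8 layers) — two sequence-to-sequence
  bidirectional LSTM stages with a per-step dense head, emitting one
  Accept/Reject label per input bin, expanded back to one label per frame.
  Bidirectionality matters here: whether the signal reappears later in the
  trace is informative about whether an intensity drop is bleaching or
  blinking.
* **`fret_cnn`** (7 layers) — an image classifier over the 32x32
  donor-versus-acceptor scatter histogram of a trace
  (`traceToScatterImage()`), which encodes channel correlation, state
  structure and noise while discarding time order.

The LSTM stages use 100 bidirectional cells per direction by default. Input
traces are binned (`binTrace()`): `nBin = 10` consecutive frames form one
input column, so a trace of `T` frames becomes an `[nBin, T/nBin]` array
per channel (two-channel traces stack the donor block above the acceptor
block). Binning trades temporal resolution for local-pattern context;
widths much below 10 starve the feature detectors in the presence of noise,
widths much above 10 inflate the per-step feature dimension. The trailing
`T mod nBin` frames are dropped to preserve bin alignment.

## Loss, training, and class weights

Training minimizes a weighted cross-entropy

$$L = -\sum_i \sum_j w_i\, Y_{ij} \log P_{ij}$$

over labels $i$ and traces $j$ (or trace-bins, for the segmenter), exposed
directly as `weightedCrossEntropy()`. The per-class weights encode the cost
asymmetry of the application and are loaded per family by
`defaultClassWeights()`:

| family | weights | rationale |
|---|---|---|
| `simreps_lstm` | `MUT = 1, WT = 1e6` | a single false mutant detection in a wild-type-only sample destroys assay specificity |
| `fret_classifier_lstm` | `ACCEPT = 1, REJECT = 1` | plain concordance with manual selection |
| `fret_segmenter_lstm` | `ACCEPT = 10, REJECT = 1` | in typical manually-segmented data the accepted segments are a small fraction of all frames |

Optimization is ADAM with initial learning rate `1e-4` and Glorot (uniform)
initialization, per-gate for the LSTM blocks, with the forget-gate bias
started at 1. Inside the training loop the batch loss and gradient are
normalized by the *total weight* in the batch, so that extreme weight
configurations such as `w_WT = 1e6` do not blow up the effective step size;
the exported `weightedCrossEntropy()` keeps the plain (unnormalized) sum.
Probabilities at true labels are floored at `1e-12`, making a
zero-probability prediction a large finite loss rather than infinity.
Dropout (rate 0.2 after each LSTM stage) uses inverted scaling, with one
mask per trace and feature held constant across time, the usual choice for
recurrent stacks. Variable-length traces in a batch are zero-padded and
masked: state updates, outputs, losses and gradients at padded steps are
all suppressed, so classification results are bit-reproducible regardless
of batch composition — verified by test. Training stops early when the
epoch loss has not improved for 5 consecutive epochs (configurable).

All randomness in a run — initialization, shuffling, dropout — derives from
the single `trainConfig()` seed; rerunning `simulate -> train -> classify`
with the same seeds reproduces decision tables exactly. The per-step LSTM
recurrences (forward and backward-through-time) run in compiled code
(`src/lstm.cpp`); analytic gradients of every layer are checked against
central finite differences in the test suite.

## Transfer learning

`transferLearn()` adapts a trained classifier or segmenter to a new
molecular system: all layers except the last `nTrainableTailLayers`
(default 3 — dropout, dense head, softmax) are frozen, and only the tail is
retrained on a small labeled set (a few hundred traces). Frozen parameters
are bit-identical before and after, and the trainable tail is a tiny
fraction of all parameters (for the 7-layer classifier, the 402-parameter
dense head out of ~338k, about 0.12%). Because backpropagation stops below
the lowest trainable layer, adaptation is also much cheaper than full
training.

## The simulator

`simulateAcceptedFret()` implements a Monte-Carlo model of high-quality
two-state smFRET traces:

* FRET efficiencies `E1, E2 ~ U(0, 1)` per trace;
* transition rates `k12, k21 ~ Exp(mean = 0.05 /frame)` per trace, run as a
  discrete-frame two-state Markov chain (per-frame switch probability
  `1 - exp(-k)`) started from its stationary distribution;
* independent photobleaching of donor and acceptor, geometric with
  per-frame rate 0.0025 (0.025 s^-1 at the default 0.1 s frame interval);
* donor = `total * (1 - E)`, acceptor = `total * E` with
  `total = 1000` AU; after acceptor bleach the donor recovers to the full
  1000 AU (energy transfer stops), after donor bleach both channels go
  dark — standard FRET photophysics;
* i.i.d. Gaussian noise per channel with s.d. a per-trace fraction of the
  total signal, drawn from `U(0.05, 0.3)` by default.

Frames are 0-based; bleach frames mark the first dark frame; masks and
segment intervals are half-open `[start, end)`. The ground-truth
`frameMask` (TRUE before the first bleach event) is what the segmenter
trains on. `simulateRejectedFret()` generates the disqualifying artifact
classes (multi-state, uncorrelated channels, low SNR, immediate bleaching,
acceptor-free), and `simulateSimreps()` generates one-channel MUT telegraph
traces and WT background behaviours (single events, rare long events,
drift).

What the simulator does *not* emulate: photoblinking, triplet states,
camera (EMCCD/sCMOS) noise statistics, spectral bleed-through, gamma
corrections, baseline drift in FRET channels, or the diversity of real
artifact morphologies. Passing the synthetic benchmarks therefore
demonstrates that the architecture, loss, optimizer and gradients are
correct and that the networks can learn the intended discriminations — it
does not certify performance on any particular experimental dataset, which
additionally depends on training-data curation.

## Benchmark conditions and numerical choices

The package's learning benchmarks (in the acceptance test suite) use
well-separated synthetic classes: accepted traces at noise fraction
0.05–0.15 versus low-SNR rejects at 0.8–0.95, 2,000 training traces, the
full 100-cell canonical architectures. We run these benchmarks on 600-frame
traces (60 LSTM steps after binning): bleaching (mean frame 400) is visible
in ~95% of traces while keeping the benchmark's turnaround practical on a
single CPU. The classifier benchmark uses the default learning rate
(`1e-4`, 10 epochs). The segmenter benchmark uses `1e-3` for 12 epochs and
uniform class weights: the 10:1 default is motivated by data in which
accepted segments are rare, whereas in this training mix ~27% of frames are
accepted and the asymmetric weight systematically drags the decision
boundary ~1 bin past the true bleach frame. Boundary recovery is scored
against the end of the longest accepted run, at the +-10 frame (one-bin)
level. The transfer-learning benchmark pretrains on one simulator regime
(fast kinetics, low-noise accepts) and adapts with ~500 traces to a shifted
regime (10x slower kinetics, accepts at intermediate noise), where the
unadapted decision boundary is poorly placed.

Other numerical conventions:

* decision rule: strict `score > 0.5` accepts; a score exactly at the
  threshold is rejected;
* FRET estimator: uncorrected proximity ratio `acceptor / (donor +
  acceptor)`, clipped to [0, 1]; frames with non-positive total are dropped
  and counted; histograms use 50 bins on [0, 1];
* two-component Gaussian fits (`fitTwoGaussians()`): Levenberg–Marquardt on
  the binned histogram with means kept in [0, 1] by a logistic
  parameterization, s.d. positive by a log parameterization,
  initialization at the two tallest histogram peaks at least 0.15 apart
  (s.d. 0.05), 5 jittered restarts; components reported in increasing order
  of mean; a fit is flagged degenerate when one component absorbs >= 95% of
  the population or collapses below s.d. 1e-4;
* kinetic idealization (`kineticSummary()`): two-means thresholding with a
  hysteresis band of +-0.25 of the level separation — a deliberately simple
  stand-in for HMM idealization, adequate for event counting and dwell
  summaries at moderate noise;
* segmenter post-processing: accepted runs shorter than 10 frames are
  removed when bin labels are expanded to frames;
* the on-disk container is a versioned single-file serialization (one group
  per movie, one dataset per trace); the delimited dialect is a long-format
  CSV written at full double precision so write/read round trips are exact.

## Limitations

The architectures are canonical small templates, not replicas of any
specific published layer tables; absolute parameter counts will differ
between implementations. The CNN is CPU-sized (8/16 filters) by default;
widths are configurable where more compute is available. The simulator's
reject classes are stylized; real training corpora should replace or
augment them where manual labels exist. No multi-state (>2) FRET fitting,
no dwell-time HMM inference, and no raw-movie processing (spot finding,
registration) are provided — traces are this package's input boundary.
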