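---
title: "Detecting driving stress from short-term physiological signals with continuous recurrence plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driving stress from short-term physiological signals with continuous recurrence plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mental stress while driving degrades attention and decision-making, and
physiological channels that a wearable can measure — skin conductance
(galvanic skin response, GSR) at the foot (FGSR) and hand (HGSR), and heart
rate (HR) — respond to it within seconds through sympathetic activation.
`contrp` implements a pipeline that classifies *short* windows (10 or 30 s)
of these three channels as **stressed** versus **relaxed**, using the kind
of protocol under which such data are collected in real traffic: a session
is one continuous recording with two rest periods bracketing alternating
city and highway driving, and a marker channel delimits the periods.  Rest
is taken as low stress, city driving as high stress; highway driving sits
in between and is excluded from the two-class problem.

The pipeline has four stages:

1. **Preprocessing** — bring all channels to a common 16 Hz rate, median
   filter, z-normalize, window with 50% overlap, label windows from the
   period annotation.
2. **Continuous recurrence plots** — turn each 1-D window into a 2-D
   image: the matrix of pairwise Euclidean distances between its
   time-delay-embedded states.
3. **Multimodal CNN** — three weight-independent convolutional branches
   (one per channel) whose pooled features are concatenated and fed to a
   single sigmoid unit giving `P(stressed)`.
4. **Evaluation** — leave-one-recording-out cross-validation, so a model
   is always tested on a session (subject) it has never seen.

A synthetic-recording generator reproduces the protocol's structure, so
every stage is testable end to end without downloading any data.

## Preprocessing

Native rates are heterogeneous: GSR channels arrive at roughly 33–35 Hz,
HR at 0.5–1 Hz.  All channels are resampled to **16 Hz**; GSR is
low-passed first (zero-phase Butterworth of order 4 with cutoff at 0.8 of
the new Nyquist) to prevent aliasing, then linearly interpolated onto the
uniform grid; HR is linearly interpolated directly.  Linear interpolation
is adequate for these slowly varying signals and keeps the operation exactly
reproducible.

A **median filter** (default 5 samples, about 0.31 s at 16 Hz) removes
spike artifacts from electrode contact and motion; the width is a
configuration parameter because no canonical value exists.  Edges are
handled by half-sample reflection, so monotone ramps pass through
unchanged.

**Z-normalization** is computed per recording and per channel over the
full recording, with the population (n) denominator.  Per-recording scope
makes amplitudes comparable across subjects without using any window-level
label information; per-window normalization would instead erase the
amplitude differences between quiescent and eventful windows that carry
class information.

**Windowing** uses fixed-length windows (10 or 30 s) starting at 0 with a
50% overlap; trailing partial windows are dropped, never padded.  A window
fully inside a rest period is labeled *relaxed*; fully inside a city
period, *stressed*.  Windows that overlap any period boundary have no
single ground truth and are discarded, as are windows in highway
(medium-stress) periods.

## Continuous recurrence plots

A scalar window `x` of length `N` is embedded with delay `tau` into
`m`-dimensional state vectors `(x[i], x[i+tau], ..., x[i+(m-1)tau])`,
giving `M = N - (m-1) tau` states.  The *continuous recurrence plot*
(Cont-RP) is the full `M x M` matrix of pairwise Euclidean distances —
a recurrence plot without the classical binarizing threshold, so the
*degree* of recurrence is retained.  Defaults are `m = 3`, `tau = 2`
samples (0.125 s at 16 Hz), producing 156 x 156 plots for 10-s windows
and 476 x 476 for 30-s windows.

Two numerical choices matter here:

* distances are kept at full floating precision — no clipping, no
  quantization;
* by default plots are **not** min-max rescaled per plot.  The underlying
  signals are already z-normalized per recording, so distances are in
  comparable units; the overall distance magnitude of a window (a flat
  rest window has uniformly small distances, an SCR-dense city window has
  large ones) is itself one of the strongest class cues, and per-plot
  rescaling erases it — during development this cost the synthetic task a
  large fraction of both training and held-out accuracy.  `rp_to_image()`
  still provides min-max scaling for rendering and for experiments that
  want scale-free inputs.

The implementation computes the plot with a vectorized distance routine
and is checked in the test suite against a naive double-loop oracle at
`1e-10`, together with its structural properties: symmetry, zero
diagonal, translation invariance, `|a|` scale equivariance, and shift
periodicity on sinusoids.

## The multimodal CNN

Each branch follows the front of the VGG16 layout: five blocks of 3 x 3
stride-1 same-padding convolutions with ReLU, two convolutions in blocks
1–2 and three in blocks 3–5, each block closed by a 2 x 2 stride-2 max
pool.  Default filter counts are `(32, 64, 128, 256, 256)`.  After block
5 a **global max pool** collapses the spatial dimensions, so each branch
emits a 256-dimensional feature vector for *any* input side of at least
32 pixels — this is what lets one architecture serve both the 156 x 156
and 476 x 476 plots and always produce a 768-dimensional concatenated
representation.  The head is one dense sigmoid unit; `P(relaxed)` is
`1 - P(stressed)` by construction, and a sample with `p >= 0.5` is called
stressed.

Training is minibatch SGD on binary cross-entropy (defaults: learning
rate 0.001, batch size 4, 15 epochs, momentum 0 — the full-scale study
protocol).  Weights are initialized He-uniform rather than with a
fan-average scheme: each branch stacks 13 ReLU convolutions, and
fan-average initialization shrinks activations by roughly
`2^(-13/2)`, leaving the pooled features near zero and the loss flat over
the first epochs.  He scaling preserves activation variance through ReLU
stacks and makes the network trainable from scratch within a small epoch
budget.  All randomness (initialization, per-epoch shuffling) derives
from one integer seed; given a seed, a training run is bit-reproducible
on a given platform.

The CNN itself is implemented in C++ (RcppArmadillo): feature maps are
stored pixel-major as `(H*W) x channels` matrices, convolutions are
lowered to BLAS GEMM via a chunked im2col (the chunking caps scratch
memory at ~64 MB so 476 x 476 inputs are safe), and arithmetic is single
precision.  Backpropagation is verified in the test suite against central
finite differences.

## Evaluation protocol

`run_cv()` performs leave-one-recording-out cross-validation: one fold
per recording, the fold's model trained from scratch (fold seed =
base seed + fold index) on all other recordings and tested on the
held-out one.  Class imbalance (city driving yields more windows than
rest) is handled by random undersampling of the majority class.  Two
balance modes exist:

* `"fold"` (default): undersample within each training fold only.  No
  information about the held-out recording can influence training — the
  leakage-safe choice, and the per-fold training-set identities are
  recorded in the report so the property is auditable.
* `"global"`: undersample once before splitting, replicating protocols
  that balance the whole dataset before cross-validation.

Metrics follow the standard formulas: accuracy, precision and recall as
percentages, F1 as a proportion, per class by role-swapping, with 0/0
denominators reported as undefined (`NA`) rather than 0.  Fold confusion
matrices are summed into an aggregated matrix from which overall metrics
are recomputed.  AUC is the rank-based (Mann-Whitney) statistic; because
no canonical aggregation exists across folds, the report carries both the
mean of per-fold AUCs and the pooled AUC over all held-out scores.
`grid_search()` evaluates a (learning rate, batch size, epochs) grid by
the same recording-wise accuracy with a deterministic first-in-grid-order
tie-break.

## The synthetic generator

`generate_recording()` emulates what the pipeline consumes, not the full
physiology:

* **Route** — seven periods (rest, city, highway, city, highway, city,
  rest), default durations 900/300/420/300/420/300/900 s, i.e. a 59-minute
  session like the real protocol.
* **GSR channels** (33 Hz) — a tonic level (per-recording baseline plus a
  state-dependent offset of 0/1.5/3 microsiemens for rest/highway/city,
  ramped over ~10 s at transitions, plus a slow random walk) superposed
  with skin conductance responses: difference-of-exponentials kernels
  (rise 0.75 s, decay 2 s — standard electrodermal phenomenology) at
  state-dependent Poisson rates (0.05/0.15/0.30 events per second for
  rest/highway/city) with log-normal amplitudes, plus Gaussian sensor
  noise and sparse spike artifacts.  FGSR and HGSR share rates but draw
  independent event timings, emulating the partial complementarity of the
  two electrode sites.  Each channel carries its event log so tests can
  verify the construction against an independent reconstruction.
* **HR channel** (1 Hz) — state-dependent baseline (75/82/92 bpm),
  respiratory sinus arrhythmia (0.25 Hz sinusoid, 3 bpm) and AR(1)
  variability.
* **Marker channel** (16 Hz) — piecewise-constant level codes 0/1/2 for
  rest/highway/city.

`make_dataset()` draws per-recording baseline offsets (FGSR 3–9, HGSR
3–18 microsiemens, HR ±12 bpm) spanning the wide between-subject spread
of real driving recordings, so recording-wise cross-validation faces
genuine between-subject variation.  A single `stress_contrast` scalar
multiplies every state-dependent difference: 1 is the calibrated
realistic contrast, larger values give a cleanly separable task, and 0
removes separability entirely — the null construction used to check that
the pipeline finds nothing when there is nothing to find.

What the generator does **not** emulate: real tonic/phasic EDA coupling,
heart-rate variability spectra, motion artifacts correlated across
channels, or sensor dropout.  Passing the synthetic end-to-end test
therefore demonstrates that the pipeline's machinery works — labeling,
recurrence representation, learning, fold hygiene — not that the
classifier would reach any particular accuracy on real recordings.

## Desk-scale validation experiment

The packaged end-to-end check (mirrored by `scripts/acceptance.R`) uses
deliberately scaled-down study conditions chosen once:

* 4 recordings, 7-period route with durations 75/60/30/60/30/60/75 s;
* high contrast (`stress_contrast = 5`) with small sensor noise
  (GSR noise 0.02, HR noise 1 bpm), the regime in which the pipeline is
  expected to recover the labels;
* 10-s windows (156 x 156 plots), about 61 labeled windows per recording;
* a thin architecture `(8, 16, 32, 64, 64)` trained 5 epochs with
  learning rate 0.005, batch size 4, plain SGD (the raw-distance plots
  carry a larger input scale than rescaled ones, so the thin network
  needs a smaller step than one might use otherwise; larger steps can
  destabilize some initializations);
* leave-one-recording-out CV in `"fold"` balance mode.

Under these conditions the held-out accuracy is required to reach 0.90,
and with `stress_contrast = 0` the same protocol must land inside the
binomial 95% band around chance.  The thin architecture and short route
keep the whole experiment at a few minutes on one CPU core; the full-size
architecture and 30-s windows are exercised separately (forward pass and
representation-dimension contracts) where their cost is seconds.

With only five training epochs from scratch, plain SGD at this scale has
visible run-to-run variance in how well the decision threshold is
calibrated for an unseen recording; ranking quality (AUC) is typically
high even when a single fold's threshold lands badly.  The packaged
conditions (contrast, noise, sample count, learning rate) were chosen so
the accuracy requirement holds with margin, but AUC is the more stable
indicator at this scale and both are reported.

## Visualization

`render_rp_image()` writes a plot as a PNG with one pixel per matrix
entry, dark blue for small distances through yellow for large ones.
`embed_2d()` projects the 768-dimensional pre-head representations to
2-D with an exact (O(n^2)) t-SNE — perplexity-calibrated Gaussian
affinities, early exaggeration, adaptive gains — implemented in the
package and seeded for determinism; the conventional scatter colors
stressed samples red and relaxed green.

## Known limitations

* The CNN is CPU-bound single-core BLAS; the full-scale protocol
  (filters up to 256, 30-s plots, 15 epochs, 9 recordings) is a
  multi-hour computation and is exposed as configuration, not exercised
  by the tests.
* The recurrence representation assumes the 16 Hz working rate; `tau` is
  counted in samples, so changing the rate changes the physical delay.
* `auc_rank()` and the metrics assume binary labels; the three-level
  protocol (including highway) is out of scope.
* Real-data readers cover the package's own directory format; physiologic
  waveform-bank formats are an extension point.
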