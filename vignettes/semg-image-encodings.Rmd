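---
title: "Image encodings and multi-stream CNNs for sEMG gesture recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image encodings and multi-stream CNNs for sEMG gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgimage)
```

## The problem and the method

Surface electromyography (sEMG) measures muscle electrical activity through
skin electrodes; multi-channel sEMG envelopes carry enough information to
decode which hand or wrist gesture a person is performing.  This package
implements a recognition pipeline that converts each short window of a
multi-channel envelope signal into three complementary two-dimensional
images and classifies the triple with a three-branch convolutional network
fused at the fully connected layers.

The three encodings capture different aspects of the same window:

* **Sigimg** (channel rearrangement): the $t_w \times C$ window is tiled
  horizontally into $C$ blocks, block $k$ being the window with its columns
  cyclically rotated by $k$.  The result is $t_w \times C^2$; every channel
  column appears exactly $C$ times and every unordered channel pair is
  column-adjacent in at least one block, so small 2-D convolution kernels
  can see every cross-channel correlation.  This preserves the raw temporal
  waveform.
* **GADF** (Gramian angular difference field): each channel is min–max
  rescaled to $[-1, 1]$ via
  $\tilde{x}_i = \frac{(x_i - \max X) + (x_i - \min X)}{\max X - \min X}$,
  mapped to polar angles $\phi_i = \arccos \tilde{x}_i \in [0, \pi]$, and
  expanded into the $n \times n$ matrix $G_{ij} = \cos(\phi_i - \phi_j)$.
  The diagonal retains the original series; off-diagonal entries encode
  pairwise temporal relations ("static" structure).
* **MTF** (Markov transition field): each channel is split into $Q$
  quantile bins, a first-order Markov transition matrix
  $W_{ab} = \Pr(\text{next bin} = b \mid \text{current bin} = a)$ is
  estimated from consecutive samples, and the field
  $M_{ij} = W_{\mathrm{bin}(x_i),\, \mathrm{bin}(x_j)}$ spreads those
  transition probabilities over all time pairs ("dynamic" structure).

Per-channel GADF and MTF subimages ($n \times n$ with $n = t_w$) are
stitched horizontally into $n \times (C\,n)$ images.  For the standard
20-sample, 10-channel configuration the three images are $20 \times 100$,
$20 \times 200$ and $20 \times 200$.

The classifier (`mscnn_spec()`) runs one convolutional branch per encoding
(two 3×3/5×5 convolutions with batch normalisation and ReLU, each followed
by 2×2 max pooling), flattens the branches to 4000 + 8000 + 8000 features,
and fuses them through fully connected layers 4096 → 2048 → classes with
dropout 0.5 before each, ending in a softmax.  Single-stream
(`sscnn_spec()`) and dual-stream (`dscnn_spec()`) ablations share the same
branch definitions with their own fusion stacks (1024/256 or 2048/512, and
4096/1024 respectively).

## Assumptions

* Input recordings are non-negative RMS-envelope-like signals, already
  segmented per subject/gesture/repetition (rest periods removed).  No
  movement-onset detection is performed.
* Windows are self-contained: GADF/MTF rescaling and binning happen per
  channel *within* each window, so encoding works online without
  recording-level statistics.  A consequence worth knowing: GADF and MTF
  are invariant to positive affine transforms of a window, so they encode
  shape, not absolute amplitude — the Sigimg stream retains amplitude.
* The train/test split is repetition-wise (`split_spec()`, default
  repetitions 1, 3–6, 8–10 vs 2 and 7), which keeps all windows of one
  movement execution on one side of the partition.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tw_ms`, `ts_ms` | 200, 100 | ms | 20-sample windows at 100 Hz; decision latency stays under the ~300 ms usability bound for myoelectric control |
| `Q` (MTF bins) | 8 | — | not fixed by the source description; 8 bins resolve envelope dynamics at $n = 20$ without emptying bins |
| `gadf_formula` | `cos_diff` | — | the cosine-of-difference matrix as printed in the source design; `sin_diff` gives the more common literature GADF |
| `lr_initial`, drops | 0.1, ÷10 at epochs 16, 24 | — | the reference schedule; kept as the default |
| `batch_size`, `epochs` | 100, 30 | — | reference values |
| `dropout` | 0.5 | — | before each fusion FC layer |
| `snr_db` (generator) | 10 | dB | a realistic envelope noise level: clearly visible noise that still leaves bursts dominant |

Desk-scale note: with Adam, an initial rate of 0.1 is unstable on small
datasets (it was presumably tuned for the full 27-subject corpus); the
package's own small-scale runs and tests use a flat `1e-3`, which lies
inside the 0.001–0.01 range the reference procedure explored before
settling its schedule.  `mscnn_spec(scale = 0.5)` halves filter counts and
fusion widths for affordable CPU training.

## Numerical choices

* Degenerate rescaling (constant series) maps to 0, the midpoint of
  $[-1, 1]$; `acos` inputs are clipped to $[-1, 1]$ at $10^{-12}$.
* Quantile bin intervals are half-open on the right, last interval closed;
  collapsed quantiles (ties) leave earlier bins empty rather than failing.
* Transition-matrix rows with no outgoing transitions are set uniform to
  $1/Q$ so row-stochasticity holds on every input.
* Final images are min–max normalised to $[0, 1]$ per image.
* Window sample counts derive from milliseconds as
  `round(ms * fs / 1000)`; incomplete tail windows are dropped, not padded.
* Wavelet denoising (`wavelet_denoise()`): db4, level 4, soft universal
  (VisuShrink) threshold with per-channel MAD noise estimate — only the
  wavelet name is fixed by the source protocol; these completions are
  standard sEMG practice.  The DWT is periodised; odd-length levels are
  padded by repeating the final sample and trimmed on reconstruction.
* Downsampling uses a zero-phase windowed-sinc FIR low-pass (cutoff 0.45
  of the target band, `8 * factor + 1` taps, reflect padding) before
  integer decimation.
* Max pooling uses floor division on odd dimensions (the reference shapes
  divide exactly, so this only matters for non-standard window sizes).
* MAC counting (`count_macs()`) counts conv and FC multiplies only; the
  published per-model MAC table could not be reproduced under any
  convention we tried, so only ordering/additivity across architectures is
  asserted, never the published numbers.

## Open design points and how they were resolved

* The exact published channel-rearrangement scheme is only constrained by
  its output size ($20 \times 100$ for $C = 10$) and the stated goal that
  every channel pair become adjacent; the cyclic-rotation tiling used here
  satisfies both and is the simplest such scheme.
* The printed Gramian matrix uses cosine differences where the wider
  literature uses sine differences; both are implemented, the printed form
  is the default.
* The printed per-subject accuracy formula contradicts its own prose; the
  prose definition (correct/total per subject, then averaged across
  subjects) is implemented.
* The transition-probability conditional is printed with ambiguous index
  roles; the standard forward estimate (row = current bin, column = next
  bin) is used.
* Batch-norm placement (conv → BN → ReLU) and dropout placement (before
  each fusion FC) are not specified in the source design; these standard
  placements are used.

## The synthetic generator: what it does and does not establish

`generate_semg()` emulates segmented Ninapro-DB1-style envelope
recordings: each gesture owns a fixed channel-activation weight vector
(drawn once per seed with a minimum pairwise angular separation of 10°);
each repetition is a held-contraction profile — a plateau with 0.3 s
raised-cosine onset/release ramps, modulated by 2–4 Gaussian-shaped
activation bursts (FWHM 0.5–2 s, random onsets) as ±15% within-repetition
fluctuation, normalised to unit mean — with log-normal per-channel
amplitude jitter (σ = 0.15) and folded Gaussian noise at the configured
SNR.  The plateau (rather than a bare sum of sparse bursts) is what makes
every 200 ms window of a repetition carry class signal, as the learnable-
signal invariant below requires; sparse bursts would leave inter-burst
windows noise-only at the 5 s default duration.  Outputs are non-negative
and deterministic per seed, independent of consumption order.
An `armband_config()` preset (8 channels, 500 Hz, 6 gestures, 30
repetitions) exercises the denoise → downsample → encode flow.

This generator produces *linearly separable-by-construction* class
structure (a nearest-centroid baseline on per-channel means must exceed
80%, and the tests verify it does).  A green learning test therefore
establishes that the encoders preserve class information and that the
network and optimiser can extract it — it does **not** establish the
published accuracy on real Ninapro DB1, which has inter-subject
variability, electrode shift, and non-stationarity the generator does not
model.  Reproducing the published benchmark numbers requires downloading
the real corpus and multi-hour training, both outside this package's test
scope.

The test suite's desk-scale learning check uses the stated synthetic
condition (5 subjects, 6 gestures, 10 repetitions, default SNR) with
repetitions shortened from the 5 s acquisition default to 1 s and a
half-width network for a single-CPU time budget; the ≥60% accuracy
threshold (chance 16.7%) is unchanged by this scaling.

## Known limitations

* No GPU path and double precision only: training the full-width model on
  the complete 27 × 52 × 10 corpus is out of desk reach.
* The MAT v5 subset reader handles real numeric matrices (plain or
  zlib-compressed), which covers Ninapro-style files; cell arrays, structs
  and sparse matrices are not supported.
* Dataset export uses CSV/JSON artifacts rather than HDF5 (no HDF5 binding
  is available in the supported R stack).
* Real-time streaming segmentation and acquisition hardware integration
  are out of scope.

## A worked desk-scale example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  synth = synth_config(subjects = 2, gestures = 4, repetitions = 10,
                       duration_s = 1, seed = 7),
  arch = "mscnn", scale = 0.25,
  training = train_config(batch_size = 50, epochs = 6, lr_initial = 1e-3,
                          lr_drop_epochs = integer(0), seed = 1),
  out_dir = "semgimage-demo")
res <- run_pipeline(cfg, verbose = TRUE)
res$report          # per-subject accuracy, precision, recall
autoplot(res$report)            # confusion matrix
autoplot(res$fit)               # training curves
```
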