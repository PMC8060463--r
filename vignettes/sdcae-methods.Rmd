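---
title: "Supervised convolutional autoencoders for seizure detection: models, data and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised convolutional autoencoders for seizure detection: models, data and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdcae)
```

## The problem

Pediatric epilepsy monitoring produces long multichannel scalp EEG records
in which short ictal (seizure) episodes are embedded in hours of
interictal background. `sdcae` classifies short raw EEG windows — 1, 2 or
4 s segments of a 23-channel, 256 Hz recording — as ictal or interictal,
using a *supervised deep convolutional autoencoder* (SDCAE): a
convolutional encoder–decoder trained **once**, jointly, on

* a classification loss (binary cross-entropy on the encoder's latent
  representation, through an MLP or a bidirectional-LSTM head), and
* a reconstruction loss (mean squared error of the decoder's output
  against the input segment),

with total loss $TL = w_c \cdot CL + w_r \cdot RL$ ($w_c = 0.5$,
$w_r = 1$). The joint objective regularizes the latent space; the matched
decoder-free convolutional baselines isolate its contribution. Four
variants are provided:

| variant       | trunk                 | head                                |
|---------------|-----------------------|-------------------------------------|
| `DCAE_MLP`    | encoder + decoder     | flatten → dense(50) → dense(32) → σ |
| `DCAE_BiLSTM` | encoder + decoder     | Bi-LSTM(50/dir) → time-avg → σ      |
| `DCNN_MLP`    | encoder only          | as above                            |
| `DCNN_BiLSTM` | encoder only          | as above                            |

## Architecture

A segment enters as a $(256 d) \times 24 \times 1$ tensor ($d$ = duration
in seconds; the 23 channels are padded with one inert zero column so the
width halves cleanly). The encoder stacks four blocks of
convolution (3×2 kernels, stride 1, same padding, ReLU) → batch
normalization → max pooling; filter counts are 32, 32, 64, 64 and pooling
windows (2,2), (2,2), (2,2), (2,3), so the width contracts
24 → 12 → 6 → 3 → 1 and time contracts by 16. For a 2-s segment the chain
is

```{r shapes}
str(infer_shapes(model_config("DCAE_BiLSTM", 2))[
  c("input", "pool1", "pool2", "pool3", "pool4", "latent", "flatten")])
```

The decoder mirrors this with four upsample → convolution blocks
((2,3) then three (2,2) nearest-neighbour upsamplings; 64, 32, 32, 1
filters), ending in a sigmoid so the reconstruction lives in $[0,1]$ like
the normalized input. The Bi-LSTM head reads the latent
$(256d/16) \times 64$ bottleneck as a sequence, runs 50 LSTM cells per
direction, concatenates the per-step outputs of both directions (100
features), averages them over time, applies dropout (rate 0.1, training
only) and maps through a single sigmoid unit.

Design points the architecture description leaves open, and how this
package resolves them:

* **Kernel orientation.** 3 along time × 2 along channels — the only
  orientation under which the stated (2,3) pooling window closes the
  24 → 1 width chain.
* **Decoder block order.** Upsample before convolution, mirroring the
  encoder's convolution-before-pooling order.
* **Upsampling mode.** Nearest-neighbour repetition (the default of the
  mainstream deep-learning frameworks, and the cheapest contract to test).
* **Batch normalization placement.** Exactly four BN layers, all in the
  encoder, between each convolution and its pooling stage; none in the
  decoder.
* **Bi-LSTM size.** "50 units" is read as 50 per direction; the dense
  output after the Bi-LSTM is a single sigmoid unit with no hidden layer.
* **Bi-LSTM reduction.** Concatenate the two directions per step, then
  average over time, then classify.

## The network engine

No deep-learning framework is used: the forward and backward passes of
every layer (same-padded convolution via cached im2col indices and BLAS
matrix products, batch normalization, max pooling with
first-occurrence-argmax gradient routing, nearest-neighbour upsampling,
dense layers, LSTM cells with full backpropagation through time) and the
Adam optimizer are implemented in vectorized R. Internally tensors are
laid out `(time, width, batch, maps)` so the im2col and batch-norm
reshapes are zero-copy. Correctness is enforced in the test suite by
brute-force oracles (scalar loops re-implementing each primitive) and a
central-difference gradient check of the full joint loss on a sub-500
parameter model at $10^{-4}$ relative tolerance. The gradient check
perturbs parameters away from their zero-bias initialization first:
at exactly zero pre-activation a ReLU sits on its kink, where the
implementation's subgradient and a symmetric difference quotient
legitimately disagree.

Numerical choices: probabilities are clipped to $[10^{-7}, 1-10^{-7}]$
inside the cross-entropy; Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-7}$; max-pool ties (rare with continuous data) route the
gradient to the earliest window position; batch-norm uses $\epsilon =
10^{-3}$ and requires batches of at least 2 in training mode (the trainer
drops a trailing batch of size 1).

**Batch-norm momentum.** Running inference statistics are exponential
moving averages with momentum 0.9. This is deliberately lower than the
0.99 some frameworks default to: with momentum $m$ the running variance
still carries a fraction $m^T$ of its arbitrary (0, 1) initialization
after $T$ optimizer steps, and at the few hundred steps of a
reduced-scale run a 0.99 momentum leaves inference-mode statistics
dominated by that initialization (training accuracy 1.0, held-out
accuracy at chance). Momentum 0.9 converges within every training length
the package targets, including the full 200-epoch protocol.

## Data preparation

Segments are cut non-overlapping; ictal windows tile each annotated
seizure from its start (trailing partial window dropped — the simplest
rule that preserves non-overlap), interictal windows tile the recording
grid and must not overlap any seizure (an optional exclusion buffer
widens the forbidden zone; default 0 s for fidelity, hygiene optional).
Seizures shorter than 10 s are discarded. The interictal class is
downsampled to the ictal count by a seeded uniform draw pooled across
subjects. Normalization is a single global z-score over all values of all
segments jointly — population standard deviation, so a two-point dataset
maps exactly to ±1 — followed by a single global min–max rescale to
$[0,1]$ (the scale the sigmoid reconstruction must match). Both steps are
fitted on the **whole assembled dataset before fold splitting**; this
reproduces the described batch-level preprocessing faithfully and
therefore leaks test-set statistics into training. The leakage is
confined to four scalars (mean, standard deviation, minimum, maximum) but
is real; a leakage-free variant (fit on training folds only) can be
composed from `normalize_dataset()` applied per split. A per-channel
z-score is available behind `per_channel = TRUE`.

Folds are stratified at the segment level over the pooled cross-patient
dataset (per-class fold sizes differ by at most one); patient-level
splitting is out of scope by design, so reported numbers measure
segment-level generalization, not cross-patient transfer.

## The synthetic generator

`generate_recording()` emulates only what the pipeline needs: 23-channel,
256 Hz signals with (a) 1/f-shaped Gaussian background noise at 20 µV
RMS and (b) a 3 Hz rhythmic component — fundamental plus decaying second
and third harmonics with a random per-channel phase, a crude
spike-and-wave surrogate — at 100 µV on 80% of channels inside annotated
seizure intervals. `make_toy_cohort()` derives per-subject seeds
(`seed + subject index`), allocates each seizure its own 120-s block and
draws durations uniformly from 15–40 s so nothing falls to the 10-s
filter. Defaults were chosen once as clearly separable at small training
scale and are not tuned per experiment.

What the generator does **not** model: real ictal electrographic
morphology and evolution, artifacts (eye blinks, EMG, electrode pops),
montage geometry, inter-subject variability beyond the seed, or
non-stationary background. Consequently, passing tests demonstrate that
the pipeline's machinery is correct and that the models can learn a
clearly separable rhythm — they say nothing about clinical performance on
real EEG, which requires the public pediatric scalp-EEG archive the I/O
layer is designed around (EDF recordings plus `chbXX-summary.txt`
annotations, 16 selected subjects as a configurable include-list).

## Training and evaluation protocol

The reference protocol trains every (variant, duration) combination for
200 epochs, batch size 32, Adam at learning rate $10^{-4}$, under
stratified 10-fold cross-validation; per fold, accuracy, sensitivity,
specificity, precision and F1 are computed on the held-out fold
(threshold 0.5, ties predicted ictal) and summarized as mean ± sd over
folds (sample sd, $n-1$). Models are rebuilt from fresh seeded
initializations per fold. The Kruskal–Wallis H test (rank-based, tie
corrected, chi-square approximation with `groups - 1` degrees of
freedom) compares per-fold metric distributions across models;
`kruskal_wallis()` accepts arbitrary group lists so that models can be
pooled into comparison groups in whichever way a study design calls
for. All identical
values across groups degenerate to $H = 0$, $p = 1$ by convention.

## Problem sizes used by the tests and the acceptance script

Full-scale training (12 combinations × 10 folds × 200 epochs on a
six-figure segment count) is a cluster-scale computation. The package's
own experiments therefore run a reduced configuration, chosen once:
5-subject synthetic cohorts, 1-s segments, a 400-segment balanced set,
convolutional filter counts divided by 8, 30 epochs, single 90/10
stratified split for the learning check and micro-scale (filters ÷16, 1–2
epochs) models for protocol-shape checks. At this scale the supervised
autoencoder separates the synthetic classes on the held-out fold (the
test suite asserts ≥90% accuracy; `scripts/acceptance.R` reports the
exact figures for a given seed). The reconstruction loss falls but
plateaus early: at initialization the sigmoid output already emits ≈0.5,
which is close to the mean of the near-symmetric normalized data, so the
initial RL nearly equals the data variance; part of that variance is
irreducible 1/f noise that no bottleneck can reconstruct, and closing
the rest requires far more weight movement than ~360 Adam steps at the
protocol's learning rate provide. The acceptance script reports the
achieved reduction per seed; it is a property of the step budget and the
noise floor, not of the architecture.

## Known limitations

* Segment-level (not event-level) evaluation; no latency or false-alarm
  rate per hour.
* The batch-level normalization leaks four global statistics across folds
  (kept for fidelity; see above).
* EDF support covers continuous, equal-rate, 16-bit recordings — the
  layout of the target archive — not EDF+ embedded annotations or
  discontinuous files.
* Only the Adam optimizer is implemented; alternatives (SGD, RMSProp,
  ADADELTA) are treated as a concluded design choice, not a protocol to
  reproduce.
* Pure-R training is CPU-bound (of the order of a second per 32-segment
  batch for the reduced 1-s models), so full-scale replication is out of
  reach here by design.
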