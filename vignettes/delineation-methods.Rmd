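---
title: "Self-supervised delineation of ECG fiducial points: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised delineation of ECG fiducial points: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgdelin)
```

## The problem

Clinical interpretation of an electrocardiogram rests on eight landmarks per
heartbeat: the onset, peak and offset of the P wave, the onset and offset of
the QRS complex with the R peak between them, and the peak and offset of the
T wave (the T onset is conventionally not annotated). Locating these
*fiducial points* — delineation — is what this package does, using a
self-supervised deep learning pipeline implemented entirely in R: the network
layers, their backward passes and the optimizers are part of the package and
are verified against finite-difference gradients in the test suite.

Expert labels are scarce (a few thousand annotated beats in public
databases), while unlabeled beats are abundant. The pipeline therefore
splits learning in two stages:

1. **Pretext stage.** Each preprocessed beat spawns four training samples:
   the original (pseudo-label 0), a noisy copy (1), an amplitude-scaled copy
   (2), and a time-reversed copy (3). A 4-class classifier trained to
   recognize which transformation was applied must learn beat morphology —
   where the waves are, how sharp the QRS is, which way time runs — without
   a single human label.
2. **Downstream stage.** The convolutional backbone of the pretext
   classifier is frozen; a fresh fully connected head is attached and
   fine-tuned to regress the eight landmark positions from expert-labeled
   beats.

## Preprocessing

Signals are denoised with a Daubechies-6 wavelet decomposition. Because no
wavelet package for R is available in this toolchain the transform is
implemented here as a maximal-overlap DWT (MODWT): it is shift-invariant,
keeps all subbands at signal length, and reconstructs exactly, so "zero the
offending subbands and invert" is a clean linear denoiser. With the default
8-level decomposition at 250 Hz, the two finest detail bands (roughly
> 31 Hz, high-frequency noise) and the deepest approximation (< 0.5 Hz,
baseline wander) are suppressed. The perfect-reconstruction property and a
direct-convolution oracle for the filter bank are both unit-tested.

Beats are cut around annotated R peaks: 100 samples before to 200 after at
250 Hz, a 1.2 s window. Sources at other sampling rates are windowed by the
equivalent time span and resampled, so the window is database-independent.
The pretext path resamples windows to length 300; the downstream path to
`l_net = 324`, the length the reference architecture's shape table is built
around (the accompanying prose says 325; 324 is used because the shape
arithmetic — repeated halving 324 → 162 → 81 — only works for 324, and the
published table is taken as authoritative). Labels map through the same
affine rule, `round(offset * target_len / window_len)` with half-away
rounding applied identically at train and evaluation time.

Downstream beats are standardized to zero mean and unit variance.
**Pretext beats are deliberately not normalized**: per-beat standardization
would cancel the scaling transformation exactly and make class 2
unlearnable. This interaction is tested.

## The network

The backbone is a one-dimensional DenseNet. A 7-tap stem convolution (64
channels) and a max pool halve the length; three dense blocks follow, each
block concatenating `n` layers of BN → ReLU → 1×1 bottleneck (4k channels) →
BN → ReLU → 3×1 convolution (k new channels) onto their input. Block sizes
(8, 4, 2) and growth rate k = 32 are the unique solution of the published
channel arithmetic (64 + 8·32 = 320, 160 + 4·32 = 288, 144 + 2·32 = 208);
the source names neither number. After each block a convolutional block
attention module (CBAM) reweights the features — channel attention
`sigmoid(MLP(avgpool) + MLP(maxpool))` with a shared reduction-r MLP
(r = 8), then spatial attention from a 3-tap convolution over the stacked
channel mean and max — and a transition layer (BN → ReLU → 1×1 convolution
halving channels → stride-2 average pool) halves both axes. Because all
attention weights are sigmoids, CBAM can only shrink magnitudes; this
contraction property is tested.

The published shape table contains one anomalous row, a pooling step that
*lengthens* the map from 20 to 21. It is reproduced as a stride-1 pool with
zero padding on both sides feeding a width-2 valid convolution to 128
channels, which lands exactly on the table's (20, 128) endpoint.

The head is a feature-pyramid regressor: the (20, 128) map is flattened at
full, half and quarter resolution (2560 / 1280 / 640), each projected to
256 with a ReLU, concatenated (768), merged to 256, and mapped to the
output — 4 logits for the pretext task or 8 positions for delineation.
Positions are regressed on a normalized scale (position / input length);
all reported errors are converted back to samples or milliseconds.

Choices the source leaves open, fixed here once: bottleneck width 4k
(DenseNet convention), stem pool max / transition pool average (DenseNet
convention), spatial-attention kernel 3 (as printed, not the 7 of the
original CBAM paper), dropout 0.2 after the neck, He initialization
throughout.

## Training

*Pretext*: k-fold cross-validation (default 5), cross-entropy, Adam at
1e-3, batch size 32, early stopping on validation loss. The reported
accuracy is the mean of per-fold best accuracies; the checkpoint is the
fold with the lowest validation loss.

*Transfer*: every convolutional and batch-norm parameter up to and
including the neck is copied and frozen — including the batch-norm running
statistics, so the backbone runs in inference mode during fine-tuning.
Freezing is enforced structurally (only head parameters ever reach the
optimizer) and verified bit-for-bit in tests. Because the backbone never
changes, its activations are computed once per fine-tuning run and cached,
which makes long head-only schedules cheap.

*Downstream*: an 8:2 beat-level train/test split, 5-fold cross-validation
inside the training portion, SGD with fixed learning rate 0.001 and
momentum 0.9 on the L1 (mean absolute error) loss, early stopping on
validation L1. With ~100 gradient steps per hundred epochs at this data
scale, SGD at 0.001 needs a long schedule; the default budget is 400 epochs
with patience 60, which the cached-feature path completes in well under a
minute per fold.

The fully supervised baseline trains the identical architecture from He
initialization with the same optimizer and budget, updating all parameters.
The comparison function runs both arms under an equal epoch budget for
several derived seeds and reports each arm's best validation L1; the
headline claim — self-supervised initialization is no worse than training
from scratch at equal budget — is asserted on the median over seeds.

## The synthetic data generator

No public ECG data ships with the package; everything is exercised on a
generator whose ground truth is known by construction. A beat is a sum of
five Gaussian bumps (P, Q, R, S, T) with typical lead-II amplitudes, widths
and timings; the R wave sits 0.4 s into a 1.2 s window so segmentation
anchors exactly 100 samples before it at 250 Hz. Peaks are the Gaussian
centers of P, R and T. Onsets and offsets are defined as `center ± 3·width`
of the outermost Gaussian of each complex: reference databases define truth
by expert annotation, which a simulator cannot imitate, and the 3-sigma
point is deterministic and captures >99% of each bump's energy. An
independent brute-force scan (first and last sample where the isolated bump
exceeds `a·exp(-4.5)`) reproduces these positions in tests.

Records concatenate jittered beats: RR intervals of 0.8 ± 0.04 s,
amplitudes and widths jittered by 10% and 5% relative sd, P and T timing
by 8 ms — magnitudes in the range of normal sinus variability, chosen once
and kept. White noise (0.02 mV) and a 0.3 Hz, 0.05 mV baseline sinusoid
exercise the denoiser: the simplest models of the two artifact classes the
wavelet recipe targets. Beat-to-beat timing jitter is what makes the
downstream task non-trivial — a constant predictor cannot track the moving
P and T waves.

What the generator does *not* emulate: pathological morphologies (ectopy,
ST deviation, atrial fibrillation), inter-patient variability, electrode
artifacts, or the ambiguity of expert annotations. Passing the synthetic
recovery tests therefore demonstrates that the pipeline is implemented
correctly and can learn morphology-conditional landmark positions — not
that it reaches any particular accuracy on real clinical data, which
requires the public databases and full-scale training.

## Evaluation statistics

Deviations are `(predicted − annotated)` positions, computed in resampled
coordinates, mapped back through `window_len / l_net` and converted at
`1000 / fs` ms per sample — so one original sample at 250 Hz is exactly
4 ms. The R peak is excluded from all reports because it anchors
segmentation. Per point, reports carry the mean and sd of signed deviations
and of absolute deviations. When a recording has two leads, both are
delineated independently and the lead with the smaller overall mean
absolute deviation is kept (ties to the first lead), mirroring how
two-lead reference annotations are used.

The cross-method comparison statistic is the **mean absolute error of the
per-point mean deviations**, averaged over whichever of the seven points a
method reports. `delineation_benchmarks()` carries the published per-point
means of seven methods plus three ablations, and the statistic is
recomputed from them in the tests. Two published cells disagree with their
own row arithmetic (a 2.84 where the means give 2.85, and an ablation-table
1.17 where the same row elsewhere gives 1.55); the package always reports
the recomputed value and documents the discrepancy rather than reproducing
it.

Agreement is visualized with Bland–Altman plots (mean difference ±
1.96·sd, the 95% limits of agreement) and least-squares regression of
predicted on annotated positions, summarized by distance from the identity
line `|slope − 1| + |intercept|`. Both have closed-form hand-computed
fixtures in the tests, plus a coverage property check that the limits
contain about 95% of Gaussian differences.

## Problem sizes and numerical notes

The desk-scale study used by the tests and the acceptance script runs 300
synthetic beats; the pretext stage sees 1,200 transformed samples in
5-fold cross-validation with up to 8 epochs; fine-tuning uses the 240-beat
training portion with 5-fold validation and a 400-epoch head-only budget;
the equal-budget comparison runs 30 epochs per arm over 3 derived seeds.
The reduced network configuration (`net_config_small()`: 16 stem channels,
growth 8, blocks (2, 2, 2), 32 neck channels) keeps the full study at a
few minutes on one core while exercising every architectural element; the
full-size configuration is validated shape-for-shape against the published
table but not trained at desk scale.

Numerical conventions: batch-norm uses eps 1e-5 and running-stat momentum
0.1; max-pool ties take the earlier position; label rounding is half away
from zero; all randomness (weights, folds, shuffling, dropout, noise draws)
derives from a single run seed, and identical seeds reproduce runs
bit-for-bit. Degenerate inputs are rejected rather than patched: zero-power
signals have no defined SNR, zero-variance windows cannot be standardized,
beats whose 3-sigma supports would disorder the fiducials raise an error.

## Known limitations

The WFDB reader covers the subset needed here (format-16 signals,
MIT-format annotations with the standard wave/beat codes); it is not a full
WFDB implementation. Real-database beat counts and record filters can only
be reproduced with the PhysioNet archives present. Training at the full
published scale (tens of thousands of beats, full-width network) is out of
desk scope; the package is sized to demonstrate correctness, not to
replicate clinical-scale error tables.
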