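# ecgdelin

Self-supervised delineation of ECG fiducial points, implemented entirely in
R — including the neural network and its training loop.

## What it does, and for whom

Automatic ECG interpretation needs the eight landmarks of each heartbeat:
P onset, P peak, P offset, QRS onset, R peak, QRS offset, T peak and
T offset. Expert-annotated beats are scarce, so this package implements a
self-supervised pipeline for researchers in biomedical signal processing
who want a fully inspectable, dependency-light reference implementation:

1. **Pretext task** — every beat spawns four pseudo-labelled samples
   (original / noise-added / amplitude-scaled / time-reversed), and a
   4-class classifier learns beat morphology with no human labels.
2. **Transfer** — the convolutional backbone is frozen bit-for-bit.
3. **Downstream task** — a fresh fully connected head regresses the eight
   landmark positions, trained with SGD (lr 0.001, momentum 0.9) on the L1
   loss with an 8:2 split and 5-fold cross-validation.

The network is a one-dimensional DenseNet: dense blocks
(BN → ReLU → 1×1 bottleneck → BN → ReLU → 3×1 conv, feature maps
concatenated; channels C_in + n·k with growth k = 32), each followed by a
convolutional block attention module,

    Mc(X) = sigmoid( W1 W0 X_avg + W1 W0 X_max )          (channel attention)
    Ms(X) = sigmoid( f3 [AvgPool(X); MaxPool(X)] )        (spatial attention)

and a transition layer (1×1 conv halving channels, stride-2 average pool).
A feature-pyramid head flattens the final (20, 128) map at full, half and
quarter resolution (2560/1280/640 → 3×256 → 768 → 256 → 8). Forward and
backward passes for every layer are hand-written in R and verified against
finite-difference gradients in the test suite.

Because PhysioNet data cannot ship with the package, a synthetic generator
produces beats as sums of Gaussian waves with analytically known fiducials
(peaks at Gaussian centers, onsets/offsets at center ± 3·width), plus RR
and morphology jitter, white noise and baseline wander; a minimal
WFDB-compatible writer/reader and a db6 MODWT wavelet denoiser complete the
pipeline. Evaluation uses the field's standard statistics: per-point signed
deviation summaries in ms (1 original sample = 4 ms at 250 Hz), the mean
absolute error of per-point mean deviations for cross-method comparison,
Bland–Altman 95% limits of agreement, and regression against the identity
line.

## Worked example

```r
library(ecgdelin)

# a synthetic record with known truth, written/read as WFDB if desired
rec <- generate_record(n_beats = 300, seed = 1)

# preprocess: denoise, window around R peaks, resample, normalize
down <- prepare_beats(rec$signal, rec$truth, fs = rec$fs, target_len = 324)

# pretext pretraining (4-class transformation recognition, 5-fold CV)
raw <- prepare_beats(rec$signal, rec$truth, fs = rec$fs, target_len = 300,
                     normalize = FALSE)
pre <- train_pretext(build_pretext_dataset(raw$x, seed = 2),
                     net_config_small(l_net = 300, head_dim = 4), seed = 3)
pre
#> <pretext_fit> mean CV accuracy 0.995 over 5 folds

# freeze the backbone, fine-tune the landmark head
model <- transfer_and_freeze(pre, l_net = 324, seed = 4)
fit <- train_downstream(model, down$x, down$y, epochs = 400,
                        patience = 60, seed = 5)
fit
#> <delineation_fit> best val L1 2.70 samples; held-out MAE 2.70 samples

# evaluation in milliseconds
report <- deviation_report(deviations_ms(fit$test_pred, fit$test_truth))
report
#> <deviation_report> MAE of mean deviation: 5.65 ms
#> # A tibble: 7 × 6
#>   point       n mean_dev sd_dev mean_abs sd_abs
#>   <fct>   <int>    <dbl>  <dbl>    <dbl>  <dbl>
#> 1 p_on       60     5.47   6.96     7.40   4.82
#> 2 p_peak     60    -3.65   7.47     6.31   5.37
#> 3 p_off      60     6.35   8.56     8.46   6.44
#> 4 qrs_on     60     1.31   3.40     2.93   2.15
#> 5 qrs_off    60    -1.96  10.1      7.54   6.98
#> 6 t_peak     60    -3.82  23.8     17.4   16.5
#> 7 t_off      60   -17.0   29.3     25.4   22.3
```

The printed numbers mean: the pretext classifier separates the four
transformations almost perfectly on held-out folds (99.5% cross-validated
accuracy); the fine-tuned head locates landmarks on held-out beats to
~2.7 resampled samples (≈ 10 ms) on average; and the per-point report
shows where the residual error lives — the sharp QRS landmarks are nearly
exact while the broad, jittered T offset dominates both bias and spread,
the same ordering reported for delineators on real data. `autoplot()`
methods draw the beat, the per-point report, Bland–Altman and regression
panels, and `tidy()`/`glance()` return everything as tibbles.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/ecgdelin.R simulate --out-dir run1 --n-beats 300 --seed 1
Rscript inst/cli/ecgdelin.R pretrain --out-dir run1 --seed 1
Rscript inst/cli/ecgdelin.R finetune --out-dir run1 --seed 1
Rscript inst/cli/ecgdelin.R evaluate --out-dir run1
```

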