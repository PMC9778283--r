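Package: ecgdelin
Title: Self-Supervised Delineation of ECG Fiducial Points
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Locates the eight clinically defined landmarks of an ECG heartbeat
    (P onset/peak/offset, QRS onset, R peak, QRS offset, T peak/offset) with a
    self-supervised deep learning pipeline implemented entirely in R. A
    transformation-recognition pretext task (noise addition, amplitude scaling,
    temporal inversion) pretrains a one-dimensional DenseNet backbone with
    convolutional block attention and a feature-pyramid regression head; the
    convolutional backbone is then frozen and the fully connected head is
    fine-tuned to regress landmark positions. Includes a synthetic beat
    generator with analytically known fiducials, a minimal WFDB-compatible
    reader/writer, Daubechies-6 wavelet denoising, and the evaluation
    statistics used in the delineation literature (signed deviation summaries,
    mean absolute error of mean deviations, Bland-Altman limits of agreement,
    regression agreement plots).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
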