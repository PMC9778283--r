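# Transformation-recognition pretext task: three signal transformations with
# automatically generated pseudo-labels (0 original, 1 noise, 2 scaling,
# 3 temporal inversion).

#' Add white Gaussian noise at a target SNR
#'
#' Noise power is scaled so the resulting signal-to-noise ratio equals
#' `snr_db`. `snr_db = Inf` returns the signal unchanged.
#'
#' @param signal Numeric vector with nonzero power.
#' @param snr_db Target SNR in dB.
#' @param seed Integer seed; the draw is deterministic given it.
#'
#' @return Noisy signal, same length.
#' @export
add_noise <- function(signal, snr_db = 15, seed = 1L) {
  p_sig <- mean(signal^2)
  if (p_sig == 0) stop_ecg("zero-power signal has no defined SNR.", "degenerate_beat")
  if (is.infinite(snr_db)) return(signal)
  noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
  signal + with_seed(seed, rnorm(length(signal), 0, noise_sd))
}

#' Scale a signal by a positive factor
#'
#' @param signal Numeric vector.
#' @param factor Positive multiplier.
#' @return The scaled signal.
#' @export
scale_signal <- function(signal, factor) {
  if (!is.numeric(factor) || factor <= 0) {
    stop_ecg("`factor` must be a positive number.", "bad_arg")
  }
  signal * factor
}

#' Reverse a signal in time
#'
#' @param signal Numeric vector.
#' @return The time-inverted signal.
#' @export
invert_time <- function(signal) rev(signal)

# One scaling factor per beat, drawn away from 1 so that scaling stays
# distinguishable from the original: uniform on [0.5, 0.8] U [1.25, 2.0].
draw_scale_factor <- function(n) {
  low <- runif(n, 0.5, 0.8)
  high <- runif(n, 1.25, 2.0)
  ifelse(runif(n) < 0.5, low, high)
}

#' Build the 4-class pretext dataset
#'
#' Every beat contributes exactly four samples: the original (label 0), a
#' noisy copy (label 1), a scaled copy (label 2) and a time-inverted copy
#' (label 3), so the dataset is class-balanced by construction and needs no
#' manual annotation. Identical copies (e.g. with `snr_db = Inf`) are kept,
#' never deduplicated: class separability comes from the transformation
#' parameters, not the builder.
#'
#' Beats must NOT be per-beat amplitude-normalized before entering this
#' function, otherwise the scaling class is unlearnable.
#'
#' @param beats Matrix (beats x length) or list of equal-length numeric
#'   vectors.
#' @param snr_db SNR of the noise transformation (default 15 dB).
#' @param factor Either `NULL` (a per-beat factor is drawn from
#'   `[0.5, 0.8] U [1.25, 2.0]`) or a fixed positive factor.
#' @param seed Integer seed for the noise and factor draws.
#'
#' @return Object of class `pretext_dataset`: list with `x` (matrix,
#'   `4 * n_beats` rows) and `label` (integer vector in 0..3).
#' @export
#' @examples
#' beats <- matrix(rnorm(5 * 300), 5, 300)
#' d <- build_pretext_dataset(beats, seed = 1)
#' table(d$label)
build_pretext_dataset <- function(beats, snr_db = 15, factor = NULL, seed = 1L) {
  if (is.list(beats)) beats <- do.call(rbind, beats)
  n <- nrow(beats)
  if (is.null(n) || n == 0) {
    return(structure(list(x = matrix(numeric(0), 0, 0), label = integer(0)),
                     class = "pretext_dataset"))
  }
  with_seed(seed, {
    factors <- if (is.null(factor)) draw_scale_factor(n) else rep(factor, n)
    noise_seeds <- sample.int(2^30, n)
    x <- matrix(0, 4 * n, ncol(beats))
    label <- integer(4 * n)
    for (i in seq_len(n)) {
      b <- beats[i, ]
      r <- (i - 1) * 4
      x[r + 1, ] <- b
      x[r + 2, ] <- add_noise(b, snr_db = snr_db, seed = noise_seeds[i])
      x[r + 3, ] <- scale_signal(b, factors[i])
      x[r + 4, ] <- invert_time(b)
      label[r + (1:4)] <- 0:3
    }
    structure(list(x = x, label = label), class = "pretext_dataset")
  })
}

#' @export
print.pretext_dataset <- function(x, ...) {
  cat("<pretext_dataset> ", nrow(x$x), " samples x ", ncol(x$x),
      " points; classes: ", paste(table(x$label), collapse = "/"), "\n", sep = "")
  invisible(x)
}
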