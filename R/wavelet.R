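# Daubechies-6 maximal-overlap DWT (MODWT) and wavelet denoising.
# The MODWT is used rather than the decimated transform because it is
# shift-invariant, keeps every subband at signal length, and reconstructs
# exactly, which makes "zero these subbands and invert" a clean linear
# denoiser. Circular boundary handling.

# Daubechies extremal-phase, 6 vanishing moments (12 taps), orthonormal
# scaling filter in h0..h11 order (sum = sqrt(2), energy = 1).
db6_scaling_filter <- function() {
  c(1.1154074335010947e-01, 4.9462389039845306e-01, 7.5113390802109536e-01,
    3.1525035170919763e-01, -2.2626469396543983e-01, -1.2976686756726194e-01,
    9.7501605587323043e-02, 2.7522865530305727e-02, -3.1582039317486030e-02,
    5.5384220116149613e-04, 4.7772575109455108e-03, -1.0773010853084796e-03)
}

db6_wavelet_filter <- function() {
  h <- db6_scaling_filter()
  L <- length(h)
  (-1)^(seq_len(L) - 1) * rev(h)
}

# Circularly filter x with taps f upsampled by 2^(j-1):
# y[t] = sum_l f[l] * x[(t - 2^(j-1) * (l-1)) mod N]
circ_filter_down <- function(x, f, j) {
  n <- length(x)
  step <- 2^(j - 1)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    idx <- (t0 - step * (l - 1L)) %% n
    y <- y + f[l] * x[idx + 1L]
  }
  y
}

# Adjoint direction used by the inverse transform:
# y[t] = sum_l f[l] * x[(t + 2^(j-1) * (l-1)) mod N]
circ_filter_up <- function(x, f, j) {
  n <- length(x)
  step <- 2^(j - 1)
  y <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    idx <- (t0 + step * (l - 1L)) %% n
    y <- y + f[l] * x[idx + 1L]
  }
  y
}

#' Maximal-overlap discrete wavelet transform (db6)
#'
#' @param x Numeric signal, length >= `2^levels`.
#' @param levels Decomposition depth.
#'
#' @return List with `details` (list of `levels` vectors, finest first) and
#'   `smooth` (the level-`levels` approximation), all of length `length(x)`.
#' @export
modwt_db6 <- function(x, levels = 8) {
  if (length(x) < 2^levels) {
    stop_ecg(
      sprintf("signal of length %d is too short for a %d-level decomposition.",
              length(x), levels),
      "short_signal"
    )
  }
  h <- db6_scaling_filter() / sqrt(2)
  g <- db6_wavelet_filter() / sqrt(2)
  v <- x
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    details[[j]] <- circ_filter_down(v, g, j)
    v <- circ_filter_down(v, h, j)
  }
  list(details = details, smooth = v, levels = levels)
}

#' Invert a db6 MODWT
#'
#' @param w Output of [modwt_db6()] (subbands may have been modified).
#' @return The reconstructed signal.
#' @export
imodwt_db6 <- function(w) {
  h <- db6_scaling_filter() / sqrt(2)
  g <- db6_wavelet_filter() / sqrt(2)
  v <- w$smooth
  for (j in rev(seq_len(w$levels))) {
    v <- circ_filter_up(v, h, j) + circ_filter_up(w$details[[j]], g, j)
  }
  v
}

#' Wavelet denoising of an ECG signal
#'
#' Decomposes the signal with a db6 MODWT, zeroes the deepest approximation
#' (baseline wander) and the finest detail subbands (high-frequency noise),
#' and reconstructs. With the defaults at 250 Hz the suppressed bands are
#' roughly < 0.5 Hz and > 31 Hz, the standard recipe for ECG.
#'
#' @param x Numeric signal (mV), length >= `2^levels`.
#' @param fs Sampling frequency in Hz (documentation only; the subband choice
#'   is expressed in levels).
#' @param levels Decomposition depth (default 8).
#' @param drop_details Indices of detail subbands to zero, finest = 1
#'   (default `c(1, 2)`).
#' @param drop_smooth Zero the deepest approximation (default `TRUE`).
#'
#' @return Denoised signal, same length as the input.
#' @export
#' @examples
#' x <- sin(2 * pi * 5 * (0:1023) / 250)
#' y <- dwt_denoise(x, fs = 250)
#' stats::cor(x, y) > 0.99
dwt_denoise <- function(x, fs = 250, levels = 8, drop_details = c(1, 2),
                        drop_smooth = TRUE) {
  w <- modwt_db6(x, levels = levels)
  for (j in drop_details) w$details[[j]] <- w$details[[j]] * 0
  if (drop_smooth) w$smooth <- w$smooth * 0
  imodwt_db6(w)
}
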