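# Beat windowing, resampling to the network input length, label mapping and
# per-beat normalization.

#' Cut a beat window around an R peak
#'
#' The window runs from `pre` samples before the R peak to `post` samples
#' after it (default 100 + 200 = 300 samples, a 1.2 s span at 250 Hz). Beats
#' whose window would cross the signal boundary are rejected, not truncated.
#'
#' @param signal Numeric vector.
#' @param r_peak 1-based R-peak sample index.
#' @param pre,post Samples kept before / after the R peak.
#'
#' @return Numeric vector of length `pre + post`, or `NULL` when the window
#'   does not fit.
#' @export
segment_beat <- function(signal, r_peak, pre = 100, post = 200) {
  start <- r_peak - pre
  end <- r_peak + post - 1
  if (start < 1 || end > length(signal)) return(NULL)
  signal[start:end]
}

# Time-based variant for sources not sampled at 250 Hz: an equivalent
# (-0.4 s, +0.8 s) span is cut and later resampled to the canonical length.
segment_beat_time <- function(signal, r_peak, fs, pre_s = 0.4, post_s = 0.8) {
  segment_beat(signal, r_peak,
               pre = as.integer(round(pre_s * fs)),
               post = as.integer(round(post_s * fs)))
}

#' Resample a beat window to a target length
#'
#' Linear interpolation on a common unit grid; endpoints are preserved
#' exactly and a constant window stays constant.
#'
#' @param window Numeric vector, length >= 2.
#' @param target_len Output length, >= 2.
#'
#' @return Numeric vector of length `target_len`.
#' @export
resample_beat <- function(window, target_len) {
  n <- length(window)
  if (n < 2) stop_ecg("window must have at least 2 samples.", "bad_arg")
  if (target_len < 2) stop_ecg("`target_len` must be at least 2.", "bad_arg")
  if (n == target_len) return(window)
  stats::approx(x = seq(0, 1, length.out = n), y = window,
                xout = seq(0, 1, length.out = target_len))$y
}

#' Map fiducial positions into resampled window coordinates
#'
#' Positions are first expressed as offsets from the window start, then
#' scaled by `target_len / window_len` and rounded half away from zero. The
#' same convention is applied at training and evaluation time.
#'
#' @param positions Named or unnamed vector of 8 fiducial sample indices
#'   (1-based, absolute).
#' @param r_peak 1-based R-peak index the window was cut around.
#' @param target_len Length of the resampled window.
#' @param pre,window_len Segmentation geometry (defaults 100 and 300).
#'
#' @return Named integer vector of 8 positions in 1-based resampled
#'   coordinates, or `NULL` when any position falls outside the window.
#' @export
map_labels <- function(positions, r_peak, target_len, pre = 100,
                       window_len = 300) {
  offset0 <- positions - (r_peak - pre)  # 0-based offsets within the window
  if (any(offset0 < 0) || any(offset0 >= window_len)) return(NULL)
  mapped0 <- round_half_away(offset0 * target_len / window_len)
  mapped0 <- pmin(mapped0, target_len - 1)
  out <- as.integer(mapped0 + 1)
  if (is.unsorted(out, strictly = TRUE)) return(NULL)
  stats::setNames(out, fiducial_names())
}

#' Normalize a beat to zero mean and unit variance
#'
#' @param segment Numeric vector with nonzero variance.
#' @return The standardized vector.
#' @export
normalize_beat <- function(segment) {
  s <- stats::sd(segment)
  if (!is.finite(s) || s == 0) {
    stop_ecg("zero-variance window cannot be normalized.", "degenerate_beat")
  }
  (segment - mean(segment)) / s
}

#' Prepare a record's beats for the network
#'
#' Runs the full preprocessing chain: optional wavelet denoising, windowing
#' around each R peak, resampling to `target_len`, label mapping, and
#' optional per-beat normalization. Beats rejected at the signal edges, with
#' out-of-window labels, or with degenerate amplitude are dropped and
#' reported by index.
#'
#' @param signal Numeric vector (one lead, mV).
#' @param fiducials Tibble of per-beat fiducials (absolute 1-based samples),
#'   e.g. the `truth` of [generate_record()] or the output of
#'   [extract_beat_fiducials()]. Rows with any `NA` are dropped.
#' @param fs Sampling frequency of `signal`.
#' @param target_len Network input length (default 324).
#' @param denoise Apply [dwt_denoise()] to the whole signal first.
#' @param normalize Standardize each beat window.
#' @param pre,post Segmentation window (samples at 250 Hz; other rates use
#'   the equivalent time span).
#'
#' @return List with `x` (beats x `target_len` matrix), `y` (beats x 8
#'   integer matrix of resampled label positions), `kept` (row indices of
#'   `fiducials` that survived) and `n_rejected`.
#' @export
prepare_beats <- function(signal, fiducials, fs = 250, target_len = 324,
                          denoise = TRUE, normalize = TRUE,
                          pre = 100, post = 200) {
  fid <- as.data.frame(fiducials)[, fiducial_names(), drop = FALSE]
  complete <- stats::complete.cases(fid)
  if (denoise) signal <- dwt_denoise(signal, fs = fs)
  window_len <- pre + post
  xs <- list(); ys <- list(); kept <- integer(0)
  for (i in which(complete)) {
    pos <- as.numeric(fid[i, ])
    r <- pos[5]
    if (fs == 250) {
      win <- segment_beat(signal, r, pre = pre, post = post)
      eff_pre <- pre; eff_len <- window_len
    } else {
      eff_pre <- as.integer(round(pre / 250 * fs))
      eff_post <- as.integer(round(post / 250 * fs))
      win <- segment_beat(signal, r, pre = eff_pre, post = eff_post)
      eff_len <- eff_pre + eff_post
    }
    if (is.null(win)) next
    lab <- map_labels(pos, r, target_len, pre = eff_pre, window_len = eff_len)
    if (is.null(lab)) next
    seg <- resample_beat(win, target_len)
    if (normalize) {
      seg <- tryCatch(normalize_beat(seg), error = function(e) NULL)
      if (is.null(seg)) next
    }
    xs[[length(xs) + 1]] <- seg
    ys[[length(ys) + 1]] <- lab
    kept <- c(kept, i)
  }
  x <- if (length(xs)) do.call(rbind, xs) else matrix(numeric(0), 0, target_len)
  y <- if (length(ys)) do.call(rbind, ys) else matrix(integer(0), 0, 8)
  colnames(y) <- fiducial_names()
  list(x = x, y = y, kept = kept, n_rejected = nrow(fid) - length(kept))
}
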