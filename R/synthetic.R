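#' Describe one component wave of a synthetic heartbeat
#'
#' A heartbeat is modelled as a sum of Gaussian bumps, one per component wave
#' (P, Q, R, S, T). Each bump contributes
#' `amplitude * exp(-(t - center)^2 / (2 * width^2))` millivolts.
#'
#' @param label One of `"P"`, `"Q"`, `"R"`, `"S"`, `"T"`.
#' @param amplitude Peak amplitude in mV (signed; Q and S are negative).
#' @param center Time of the peak in seconds from the start of the beat window.
#' @param width Gaussian standard deviation in seconds; must be positive.
#'
#' @return A one-row tibble with columns `label`, `amplitude`, `center`, `width`.
#' @export
#' @examples
#' wave_spec("R", 1.0, 0.4, 0.012)
wave_spec <- function(label, amplitude, center, width) {
  label <- match.arg(label, c("P", "Q", "R", "S", "T"))
  if (!is.numeric(width) || width <= 0) {
    stop_ecg("`width` must be a positive number of seconds.", "bad_wave")
  }
  tibble(label = label, amplitude = amplitude, center = center, width = width)
}

#' Default wave layout of a normal sinus beat
#'
#' Amplitudes and widths are typical lead-II values; the R wave sits at 0.4 s
#' so that a 1.2 s window at 250 Hz puts it exactly 100 samples after the
#' window start, matching the segmentation convention used downstream.
#'
#' @return A tibble of five [wave_spec()] rows in P, Q, R, S, T order.
#' @export
default_beat_waves <- function() {
  dplyr::bind_rows(
    wave_spec("P", 0.15, 0.22, 0.020),
    wave_spec("Q", -0.10, 0.36, 0.008),
    wave_spec("R", 1.00, 0.40, 0.012),
    wave_spec("S", -0.15, 0.44, 0.008),
    wave_spec("T", 0.30, 0.70, 0.040)
  )
}

validate_waves <- function(waves) {
  req <- c("label", "amplitude", "center", "width")
  if (!all(req %in% names(waves))) {
    stop_ecg("waves must have columns label, amplitude, center, width.", "bad_wave")
  }
  if (any(waves$width <= 0)) stop_ecg("wave widths must be positive.", "bad_wave")
  ord <- match(waves$label, c("P", "Q", "R", "S", "T"))
  if (anyNA(ord) || is.unsorted(ord, strictly = TRUE)) {
    stop_ecg("waves must appear in strict P < Q < R < S < T order.", "bad_wave")
  }
  if (is.unsorted(waves$center, strictly = TRUE)) {
    stop_ecg("wave centers must be strictly increasing.", "bad_wave")
  }
  invisible(waves)
}

# Ground-truth fiducials of a Gaussian-bump beat, in seconds.
# Onsets/offsets are center -/+ 3*width of the outermost Gaussian of the
# complex; peaks are the Gaussian centers of P, R and T.
wave_truth_seconds <- function(waves) {
  w <- function(lab) waves[waves$label == lab, , drop = FALSE]
  need <- function(lab) {
    x <- w(lab)
    if (nrow(x) == 0) stop_ecg(paste0("wave '", lab, "' is required."), "bad_wave")
    x
  }
  p <- need("P"); r <- need("R"); t <- need("T")
  qrs <- waves[waves$label %in% c("Q", "R", "S"), , drop = FALSE]
  first_qrs <- qrs[1, ]; last_qrs <- qrs[nrow(qrs), ]
  c(
    p_on    = p$center - 3 * p$width,
    p_peak  = p$center,
    p_off   = p$center + 3 * p$width,
    qrs_on  = first_qrs$center - 3 * first_qrs$width,
    r_peak  = r$center,
    qrs_off = last_qrs$center + 3 * last_qrs$width,
    t_peak  = t$center,
    t_off   = t$center + 3 * t$width
  )
}

truth_to_samples <- function(truth_sec, fs, length) {
  pos <- round_half_away(truth_sec * fs) + 1  # 1-based sample indices
  pos <- pmin(pmax(pos, 1), length)
  if (is.unsorted(pos, strictly = TRUE)) {
    stop_ecg(
      "3-sigma supports of adjacent waves invert the fiducial ordering.",
      "fiducial_order"
    )
  }
  stats::setNames(as.integer(pos), fiducial_names())
}

gaussian_mixture <- function(t_sec, waves) {
  out <- numeric(length(t_sec))
  for (i in seq_len(nrow(waves))) {
    out <- out + waves$amplitude[i] *
      exp(-(t_sec - waves$center[i])^2 / (2 * waves$width[i]^2))
  }
  out
}

#' Generate one synthetic heartbeat with known fiducials
#'
#' Samples a sum-of-Gaussians beat on a uniform grid and records the ground
#' truth: peaks at the P/R/T Gaussian centers, onsets and offsets at
#' `center -/+ 3 * width` of the outermost Gaussian of each complex (clipped
#' to the window). White Gaussian noise of standard deviation `noise_sd` is
#' added on top. Deterministic for a given `seed`.
#'
#' @param waves Wave table as returned by [default_beat_waves()].
#' @param fs Sampling frequency in Hz.
#' @param length Number of samples in the beat window (>= 2).
#' @param noise_sd Standard deviation of additive white noise, in mV.
#' @param seed Integer seed controlling the noise draw.
#'
#' @return An object of class `synthetic_beat`: a list with `samples` (mV),
#'   `fs`, `truth` (named integer vector of the 8 fiducials, 1-based sample
#'   indices), `waves` and `seed`.
#' @export
#' @examples
#' b <- generate_beat(noise_sd = 0)
#' which.max(b$samples) == b$truth[["r_peak"]]
generate_beat <- function(waves = default_beat_waves(), fs = 250, length = 300,
                          noise_sd = 0, seed = 1L) {
  if (length < 2) stop_ecg("`length` must be at least 2 samples.", "bad_arg")
  if (fs <= 0) stop_ecg("`fs` must be positive.", "bad_arg")
  validate_waves(waves)
  truth <- truth_to_samples(wave_truth_seconds(waves), fs, length)
  t_sec <- (seq_len(length) - 1) / fs
  samples <- gaussian_mixture(t_sec, waves)
  if (noise_sd > 0) {
    samples <- samples + with_seed(seed, rnorm(length, 0, noise_sd))
  }
  structure(
    list(samples = samples, fs = fs, truth = truth, waves = waves,
         seed = as.integer(seed)),
    class = "synthetic_beat"
  )
}

#' @export
print.synthetic_beat <- function(x, ...) {
  cat("<synthetic_beat> ", length(x$samples), " samples @ ", x$fs, " Hz\n", sep = "")
  print(x$truth)
  invisible(x)
}

# Draw one jittered copy of the wave table. QRS timing stays fixed (the R
# peak anchors segmentation); P and T centers, all amplitudes and all widths
# vary beat to beat the way real morphology does.
jitter_waves <- function(waves, amp_jitter, center_jitter, width_jitter) {
  w <- waves
  n <- nrow(w)
  w$amplitude <- w$amplitude * (1 + rnorm(n, 0, amp_jitter))
  w$width <- w$width * pmax(0.3, 1 + rnorm(n, 0, width_jitter))
  shift <- rnorm(n, 0, center_jitter)
  shift[w$label %in% c("Q", "R", "S")] <- 0
  w$center <- w$center + shift
  w
}

#' Generate a synthetic ECG record with per-beat ground truth
#'
#' Concatenates `n_beats` jittered copies of the beat template at jittered RR
#' intervals, optionally adding baseline wander (a low-frequency sinusoid)
#' and white noise. Every beat's fiducials are known by construction and
#' returned as absolute sample positions.
#'
#' @param n_beats Number of beats (>= 1).
#' @param rr_mean,rr_sd Mean and standard deviation of the RR interval in
#'   seconds. `rr_mean` must exceed the temporal span of the beat template.
#' @param waves Beat template, see [default_beat_waves()].
#' @param fs Sampling frequency in Hz.
#' @param noise_sd White-noise standard deviation in mV.
#' @param baseline_amplitude,baseline_freq Amplitude (mV) and frequency (Hz,
#'   < 0.5) of the baseline-wander sinusoid; amplitude 0 disables it.
#' @param amp_jitter,center_jitter,width_jitter Per-beat morphological
#'   variability: relative sd of amplitudes and widths, absolute sd (seconds)
#'   of P/T timing.
#' @param lead_in,tail_pad Seconds of signal kept before the first R peak and
#'   after the last one. Shrinking `lead_in` below the segmentation pre-window
#'   makes edge beats unrecoverable, which is occasionally useful in tests.
#' @param seed Integer seed; the full record is deterministic given it.
#'
#' @return An object of class `synthetic_record`: list with `signal` (mV),
#'   `fs`, `truth` (tibble: `beat` plus one column per fiducial, absolute
#'   1-based sample indices), and `seed`.
#' @export
#' @examples
#' rec <- generate_record(n_beats = 3, rr_sd = 0, noise_sd = 0, seed = 2)
#' diff(rec$truth$r_peak)
generate_record <- function(n_beats, rr_mean = 0.8, rr_sd = 0.04,
                            waves = default_beat_waves(), fs = 250,
                            noise_sd = 0.02,
                            baseline_amplitude = 0.05, baseline_freq = 0.3,
                            amp_jitter = 0.10, center_jitter = 0.008,
                            width_jitter = 0.05,
                            lead_in = 0.5, tail_pad = 0.8, seed = 1L) {
  if (n_beats < 1) stop_ecg("`n_beats` must be at least 1.", "bad_arg")
  validate_waves(waves)
  span <- max(waves$center + 3 * waves$width) - min(waves$center - 3 * waves$width)
  if (rr_mean < span) {
    stop_ecg(
      sprintf("rr_mean (%.3f s) is smaller than the beat template span (%.3f s).",
              rr_mean, span),
      "bad_arg"
    )
  }
  with_seed(seed, {
    rr <- rr_mean + rnorm(n_beats - 1, 0, rr_sd)
    rr <- pmax(rr, span)  # never let beats overlap their 3-sigma supports
    r_times <- lead_in + c(0, cumsum(rr))
    beat_waves <- lapply(seq_len(n_beats), function(i) {
      for (try in 1:20) {
        w <- jitter_waves(waves, amp_jitter, center_jitter, width_jitter)
        ok <- tryCatch({
          validate_waves(w)
          TRUE
        }, error = function(e) FALSE)
        if (ok) return(w)
      }
      stop_ecg("could not draw an order-preserving jittered beat.", "fiducial_order")
    })
    r_template <- waves$center[waves$label == "R"]
    n <- as.integer(ceiling((r_times[n_beats] + tail_pad) * fs))
    t_sec <- (seq_len(n) - 1) / fs
    signal <- numeric(n)
    truth_rows <- vector("list", n_beats)
    for (i in seq_len(n_beats)) {
      w <- beat_waves[[i]]
      w$center <- w$center + (r_times[i] - r_template)
      signal <- signal + gaussian_mixture(t_sec, w)
      tr <- round_half_away(wave_truth_seconds(w) * fs) + 1
      if (is.unsorted(tr, strictly = TRUE)) {
        stop_ecg("jittered beat lost its fiducial ordering.", "fiducial_order")
      }
      truth_rows[[i]] <- as.integer(tr)
    }
    if (baseline_amplitude > 0) {
      phase <- runif(1, 0, 2 * pi)
      signal <- signal + baseline_amplitude * sin(2 * pi * baseline_freq * t_sec + phase)
    }
    if (noise_sd > 0) signal <- signal + rnorm(n, 0, noise_sd)
    truth <- as_tibble(do.call(rbind, truth_rows), .name_repair = "minimal")
    names(truth) <- fiducial_names()
    truth <- dplyr::mutate(truth, beat = dplyr::row_number(), .before = 1)
    structure(
      list(signal = signal, fs = fs, truth = truth, seed = as.integer(seed)),
      class = "synthetic_record"
    )
  })
}

#' @export
print.synthetic_record <- function(x, ...) {
  cat("<synthetic_record> ", length(x$signal), " samples @ ", x$fs, " Hz, ",
      nrow(x$truth), " beats\n", sep = "")
  invisible(x)
}
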