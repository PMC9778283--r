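# Synthetic beat and record generation: analytic ground truth, determinism,
# fiducial ordering.

test_that("a lone Gaussian peaks at its center and truth marks it", {
  waves <- wave_spec("R", 1.0, 0.4, 0.01)
  # need P and T for a full truth vector; park them far away and tiny
  waves <- dplyr::bind_rows(wave_spec("P", 0.1, 0.1, 0.01), waves,
                            wave_spec("T", 0.1, 0.7, 0.01))
  b <- generate_beat(waves, fs = 250, length = 300, noise_sd = 0)
  # 0-based round(0.4 * 250) = 100 -> 1-based 101
  expect_identical(which.max(b$samples), 101L)
  expect_identical(unname(b$truth[["r_peak"]]), 101L)
})

test_that("onsets and offsets sit at center -/+ 3 widths (brute force)", {
  p <- list(a = 0.2, mu = 0.2, b = 0.02)
  waves <- dplyr::bind_rows(wave_spec("P", p$a, p$mu, p$b),
                            wave_spec("R", 1.0, 0.4, 0.01),
                            wave_spec("T", 0.2, 0.7, 0.03))
  beat <- generate_beat(waves, fs = 250, length = 300, noise_sd = 0)
  # brute-force scan of the isolated P Gaussian against the 3-sigma level;
  # the boundary samples sit exactly on the level, so compare with a
  # one-ulp tolerance
  t_sec <- (0:299) / 250
  iso <- p$a * exp(-(t_sec - p$mu)^2 / (2 * p$b^2))
  above <- which(iso >= p$a * exp(-4.5) * (1 - 1e-9))
  expect_equal(unname(beat$truth[["p_on"]]), min(above))
  expect_equal(unname(beat$truth[["p_off"]]), max(above))
  # and the frozen arithmetic: round((0.2 -/+ 0.06) * 250) = 35 / 65 0-based
  expect_identical(unname(beat$truth[["p_on"]]), 36L)
  expect_identical(unname(beat$truth[["p_off"]]), 66L)
})

test_that("beat generation is deterministic given the seed", {
  b1 <- generate_beat(noise_sd = 0.05, seed = 7)
  b2 <- generate_beat(noise_sd = 0.05, seed = 7)
  b3 <- generate_beat(noise_sd = 0.05, seed = 8)
  expect_identical(b1$samples, b2$samples)
  expect_false(identical(b1$samples, b3$samples))
})

test_that("fiducial ordering is validated and inversions rejected", {
  # a P wave so wide that its offset crosses the QRS onset
  waves <- dplyr::bind_rows(wave_spec("P", 0.2, 0.30, 0.04),
                            wave_spec("Q", -0.1, 0.36, 0.008),
                            wave_spec("R", 1.0, 0.40, 0.012),
                            wave_spec("T", 0.3, 0.70, 0.04))
  expect_error(generate_beat(waves), class = "ecgdelin_fiducial_order")
})

test_that("every emitted record beat keeps the fiducial ordering", {
  rec <- generate_record(n_beats = 40, seed = 21)
  m <- as.matrix(rec$truth[, fiducial_names()])
  expect_true(all(apply(m, 1, function(r) all(diff(r) > 0))))
})

test_that("zero RR jitter puts R peaks exactly rr_mean * fs apart", {
  rec <- generate_record(n_beats = 3, rr_mean = 0.8, rr_sd = 0,
                         noise_sd = 0, seed = 2)
  expect_true(all(diff(rec$truth$r_peak) == 200L))
})

test_that("noise-free peaks are recovered by argmax over 3-sigma support", {
  rec <- generate_record(n_beats = 10, noise_sd = 0, baseline_amplitude = 0,
                         amp_jitter = 0, center_jitter = 0, width_jitter = 0,
                         seed = 5)
  for (i in seq_len(10)) {
    r <- rec$truth$r_peak[i]
    win <- (r - 10):(r + 10)
    expect_equal(win[which.max(rec$signal[win])], r)
  }
})

test_that("records differ across seeds and reproduce within a seed", {
  r1 <- generate_record(20, seed = 1)
  r2 <- generate_record(20, seed = 1)
  r3 <- generate_record(20, seed = 2)
  expect_identical(r1$signal, r2$signal)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("an rr_mean shorter than the beat template span is rejected", {
  expect_error(generate_record(3, rr_mean = 0.3),
               class = "ecgdelin_bad_arg")
})
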