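# Windowing, resampling, label mapping and normalization.

test_that("segment_beat cuts [r - 100, r + 200) and rejects edge beats", {
  x <- seq_len(1000)
  w <- segment_beat(x, 501)  # 1-based r at 0-based index 500
  expect_length(w, 300)
  expect_equal(w[1], 401)    # 0-based 400
  expect_equal(w[300], 700)
  expect_null(segment_beat(x, 51))
  expect_null(segment_beat(x, 900))
  # 300 samples at 250 Hz span 1.2 s
  expect_equal(300 / 250, 1.2)
})

test_that("resampling preserves constants, endpoints and round-trips", {
  expect_equal(resample_beat(rep(2.5, 300), 324), rep(2.5, 324))
  beat <- generate_beat(noise_sd = 0)$samples
  up <- resample_beat(beat, 324)
  expect_equal(up[1], beat[1])
  expect_equal(up[324], beat[300])
  back <- resample_beat(up, 300)
  expect_lt(max(abs(back - beat)), 0.01 * diff(range(beat)))
  expect_error(resample_beat(beat, 1), class = "ecgdelin_bad_arg")
})

test_that("label mapping follows the affine formula with half-away rounding", {
  # anchor: the R peak itself maps to round(100 * 324 / 300) = 108 (0-based)
  lab <- map_labels(c(441, 446, 451, 485, 500, 505, 530, 540),
                    r_peak = 500, target_len = 324)
  expect_identical(unname(lab[["r_peak"]]), 109L)  # 108 0-based
  # window start maps to 0 (1 in 1-based coordinates)
  lab0 <- map_labels(c(400, 446, 451, 485, 500, 505, 530, 540),
                     r_peak = 500, target_len = 324)
  expect_identical(unname(lab0[["p_on"]]), 1L)
  # hand-computed offsets at 250 Hz: ms [-60,-40,-20,0,+20,+120,+160] are
  # offsets 85,90,95,100,105,130,140 -> x 1.08 -> 92,97,103,108,113,140,151
  pos <- 500 + c(-15, -10, -5, 0, 5, 30, 40)
  lab2 <- map_labels(c(pos[1:4], 500 + 2, pos[5:7]) |> sort(),
                     r_peak = 500, target_len = 324)
  expect_identical(unname(lab2),
                   c(92L, 97L, 103L, 108L, 110L, 113L, 140L, 151L) + 1L)
  # positions outside the window reject the beat
  expect_null(map_labels(c(399, 446, 451, 485, 500, 505, 530, 540),
                         r_peak = 500, target_len = 324))
})

test_that("mapped labels stay strictly increasing for accepted beats", {
  rec <- generate_record(30, seed = 17)
  prep <- prepare_beats(rec$signal, rec$truth, fs = 250, target_len = 324)
  expect_true(all(apply(prep$y, 1, function(r) all(diff(r) > 0))))
})

test_that("normalization gives zero mean unit sd and affine invariance", {
  b <- generate_beat(noise_sd = 0.01, seed = 2)$samples
  z <- normalize_beat(b)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-6)
  expect_equal(normalize_beat(3 * b + 0.7), z, tolerance = 1e-9)
  expect_error(normalize_beat(rep(1, 300)),
               class = "ecgdelin_degenerate_beat")
})

test_that("segmentation recovers all interior beats and counts rejections", {
  rec <- generate_record(50, seed = 8)
  prep <- prepare_beats(rec$signal, rec$truth, fs = 250, target_len = 300)
  # brute-force enumeration of windows that fit inside the signal
  fits <- sum(rec$truth$r_peak - 100 >= 1 &
                rec$truth$r_peak + 199 <= length(rec$signal))
  expect_equal(nrow(prep$x), fits)
  expect_equal(prep$n_rejected, 50 - fits)
  # a short lead-in makes the first beat unrecoverable
  rec2 <- generate_record(10, lead_in = 0.2, seed = 8)
  prep2 <- prepare_beats(rec2$signal, rec2$truth, fs = 250, target_len = 300)
  expect_equal(nrow(prep2$x), 9)
  expect_equal(prep2$kept, 2:10)
})

test_that("the preprocessing chain is deterministic", {
  rec <- generate_record(12, seed = 6)
  p1 <- prepare_beats(rec$signal, rec$truth, fs = 250, target_len = 324)
  p2 <- prepare_beats(rec$signal, rec$truth, fs = 250, target_len = 324)
  expect_identical(p1, p2)
})

test_that("non-250 Hz sources are windowed by time span", {
  # a 1.2 s beat at 360 Hz has 432 samples; labels map through the same
  # affine rule with the wider window
  fs <- 360
  rec <- generate_record(12, fs = fs, seed = 10)
  prep <- prepare_beats(rec$signal, rec$truth, fs = fs, target_len = 300)
  expect_equal(ncol(prep$x), 300)
  expect_gt(nrow(prep$x), 0)
  expect_true(all(apply(prep$y, 1, function(r) all(diff(r) > 0))))
})
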