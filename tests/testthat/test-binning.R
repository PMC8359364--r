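test_that("zero-median rescaling shifts and nothing else", {
  s <- resp_signal(0:2, c(1, 2, 3))
  expect_equal(rescale_to_zero_median(s)$amplitude, c(-1, 0, 1))
  s2 <- rescale_to_zero_median(s)
  expect_equal(rescale_to_zero_median(s2)$amplitude, s2$amplitude) # idempotent
  s3 <- resp_signal(0:2, c(0, 0, 10))
  expect_equal(rescale_to_zero_median(s3)$amplitude, c(0, 0, 10))
  expect_error(rescale_to_zero_median(resp_signal(1, 1)[0, ]), "empty")
})

test_that("moving-average smoother is symmetric and preserves constants", {
  const <- resp_signal(seq(0, 5, by = 0.05), rep(3.2, 101), fs = 20)
  expect_equal(smooth_signal(const)$amplitude, rep(3.2, 101))

  # unit impulse at 20 Hz: interior taps of the 1-s window are 1/20
  y <- rep(0, 201); y[101] <- 1
  imp <- smooth_signal(resp_signal(seq(0, 10, by = 0.05), y, fs = 20))
  expect_equal(imp$amplitude[101 + (-9:9)], rep(1 / 20, 19))
  expect_equal(imp$amplitude[101 + c(-10, 10)], rep(1 / 40, 2))
  expect_equal(imp$amplitude[101 + c(-12, 12)], rep(0, 2))
  # symmetric response implies no time shift
  expect_equal(imp$amplitude[101 + 1:10], imp$amplitude[101 - 1:10])

  expect_error(smooth_signal(const, window_s = 0), "window_s")
})

test_that("minimal peak distance follows the 45 bpm ceiling", {
  expect_identical(min_peak_distance_samples(20, 45), 26L)
  expect_identical(min_peak_distance_samples(2, 45), 2L)
  expect_identical(min_peak_distance_samples(20, 60), 20L)
  expect_identical(min_peak_distance_samples(0.1, 45), 1L) # floor, never 0
  expect_error(min_peak_distance_samples(0), "fs")
})

test_that("two-pass extrema detection sets the prominence threshold from the median swing", {
  s <- sine_signal(rate_bpm = 15, fs = 20, duration_s = 90)
  ext <- detect_extrema(s, min_peak_distance_samples(20))
  # swing from -1 to +1 is 2; threshold is a quarter of the median swing
  expect_equal(ext$prominence_threshold, 0.5)
  expect_equal(length(ext$maxima_idx), 23) # peaks at t = 1, 5, ..., 89
  expect_equal(length(ext$minima_idx), 22) # troughs at t = 3, 7, ..., 87

  # a small ripple on each cycle is rejected by the prominence pass
  t <- s$time_s
  ripple <- s$amplitude + 0.1 * sin(2 * pi * t * 15 / 60 * 6)
  sr <- resp_signal(t, ripple, fs = 20)
  extr <- detect_extrema(sr, min_peak_distance_samples(20))
  expect_equal(length(extr$maxima_idx), 23)

  expect_error(detect_extrema(resp_signal(t, rep(0, length(t)), fs = 20)),
               "no breathing")
})

test_that("alternation correction keeps the more extreme duplicate", {
  t <- 0:5
  y <- c(-1, 0.8, 1.0, -0.9, 0.7, -0.5)
  s <- resp_signal(t, y)
  # min, max(0.8), max(1.0), min: the higher maximum survives
  e <- manual_extrema(s, minima_t = c(0, 3), maxima_t = c(1, 2))
  ce <- correct_alternation(e, s)
  expect_identical(ce$maxima_idx, 3L)
  expect_identical(ce$minima_idx, c(1L, 4L))

  # already alternating input is untouched
  e2 <- manual_extrema(s, minima_t = c(0, 3), maxima_t = c(2, 4))
  ce2 <- correct_alternation(e2, s)
  expect_identical(ce2$minima_idx, e2$minima_idx)
  expect_identical(ce2$maxima_idx, e2$maxima_idx)

  # min(-1.0), min(-0.4), max: the lower minimum survives
  y3 <- c(-1.0, -0.4, 1, 0, 0, 0)
  s3 <- resp_signal(t, y3)
  e3 <- manual_extrema(s3, minima_t = c(0, 1), maxima_t = 2)
  ce3 <- correct_alternation(e3, s3)
  expect_identical(ce3$minima_idx, 1L)
})

test_that("phase bins split segments 1-40 / 41-100 with the stated boundaries", {
  # symmetric triangle wave, extrema known exactly
  t <- (0:160) / 20
  y <- 1 - 2 * abs((t / 4) %% 1 - 0.5) # troughs at 0, 4, 8; peaks at 2, 6
  s <- resp_signal(t, y, fs = 20)
  e <- manual_extrema(s, minima_t = c(0, 4, 8), maxima_t = c(2, 6))
  ph <- assign_phase_bins(s, e)

  at_max <- ph$bin[ph$time_s == 2]
  expect_identical(at_max, 41L) # a sample exactly at a maximum starts expiration
  expect_identical(ph$bin[ph$time_s == 0], 1L)
  # midway through inspiration: 1 + floor(40 * 0.5) = 21
  expect_identical(ph$bin[ph$time_s == 1], 21L)
  # midway through expiration: 41 + floor(60 * 0.5) = 71
  expect_identical(ph$bin[ph$time_s == 3], 71L)
  expect_true(all(ph$accepted == (ph$bin >= 41 & ph$bin <= 100)))
  # symmetric wave: half the assigned samples are accepted
  expect_equal(mean(ph$accepted[ph$bin > 0]), 0.5, tolerance = 0.02)
})

test_that("a 40:60 inspiration:expiration waveform yields 60% acceptance", {
  pair <- clean_pair(seed = 3, duration_s = 90, noise_sd = 0.02)
  ph <- bin_phases(pair$camera)
  frac <- mean(ph$accepted[ph$bin > 0])
  expect_equal(100 * frac, 60, tolerance = 2 / 60) # within 2 percentage points
})

test_that("full chain finds exactly one extremum pair per breathing cycle", {
  lat <- gen_breathing_waveform(breathing_params(duration_s = 90,
                                                 rate_jitter = 0.05, seed = 8))
  n_cycles <- length(attr(lat, "cycle_starts")) - 1L
  pair <- gen_modality_pair(lat, seed = 9)
  sm <- smooth_signal(rescale_to_zero_median(pair$camera))
  ext <- correct_alternation(detect_extrema(sm), sm)
  expect_equal(length(ext$maxima_idx), n_cycles, tolerance = 0.05)
  expect_true(all(diff(sort(c(ext$minima_t, ext$maxima_t))) > 0))
})

test_that("single-sample outliers below a quarter of the swing barely move the bins", {
  pair <- clean_pair(seed = 5, duration_s = 90)
  cam <- pair$camera
  ph0 <- bin_phases(cam)
  set.seed(21)
  idx <- sample.int(nrow(cam), 6)
  spiked <- cam
  spiked$amplitude[idx] <- spiked$amplitude[idx] +
    0.2 * sample(c(-1, 1), 6, TRUE) # swing is 1, spikes at 0.2 < 0.25
  ph1 <- bin_phases(spiked)
  both <- ph0$bin > 0 & ph1$bin > 0
  expect_lte(max(abs(ph0$bin[both] - ph1$bin[both])), 1)
})

test_that("slow baseline drift leaves the accepted-sample set nearly unchanged", {
  pair <- clean_pair(seed = 6, duration_s = 90)
  cam <- pair$camera
  ph0 <- bin_phases(cam)
  drifted <- cam
  # amplitude 0.5 x swing, period 20 s = 5 cycles at 15 bpm
  drifted$amplitude <- drifted$amplitude + 0.5 * sin(2 * pi * drifted$time_s / 20)
  ph1 <- bin_phases(drifted)
  changed <- mean(ph0$accepted != ph1$accepted)
  expect_lt(changed, 0.05)
})

test_that("cycle-mode binning spreads 100 bins over the full cycle", {
  t <- (0:160) / 20
  y <- 1 - 2 * abs((t / 4) %% 1 - 0.5)
  s <- resp_signal(t, y, fs = 20)
  e <- manual_extrema(s, minima_t = c(0, 4, 8), maxima_t = c(2, 6))
  ph <- assign_phase_bins(s, e, method = "cycle")
  expect_identical(ph$bin[ph$time_s == 0], 1L)
  expect_identical(ph$bin[ph$time_s == 2], 51L) # halfway through the cycle
  # bins 41-100 cover the last 60% of the cycle regardless of waveform shape
  expect_equal(mean(ph$accepted[ph$bin > 0]), 0.6, tolerance = 0.03)
})

test_that("acquisition events inherit the nearest sample's label", {
  t <- (0:16) / 2
  y <- 1 - 2 * abs((t / 4) %% 1 - 0.5)
  s <- resp_signal(t, y, fs = 2)
  e <- manual_extrema(s, minima_t = c(0, 4, 8), maxima_t = c(2, 6))
  ph <- assign_phase_bins(s, e)

  lab <- label_acquisition(ph, ph$time_s)
  expect_identical(lab$bin, ph$bin)
  expect_identical(lab$accepted, ph$accepted)

  # an exact midpoint tie goes to the earlier sample
  tie <- label_acquisition(ph, 2.25)
  expect_identical(tie$bin, ph$bin[ph$time_s == 2])

  outside <- label_acquisition(ph, c(-1, 9))
  expect_identical(outside$bin, c(0L, 0L))
  expect_false(any(outside$accepted))

  empty <- label_acquisition(ph, numeric())
  expect_identical(nrow(empty), 0L)
})
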