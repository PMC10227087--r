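# Oscillogram construction: band-pass, prominence-based pulse averaging,
# endpoint exclusion, normalization, subject screening.

test_that("band-pass rejects DC, keeps the cardiac band, kills drift", {
  fs <- 30
  t5 <- seq(0, 5 - 1 / fs, by = 1 / fs)
  expect_true(all(abs(bandpass_ppg(rep(5, length(t5)), fs)) < 1e-9))
  y <- bandpass_ppg(sin(2 * pi * 1.2 * t5), fs)
  expect_equal(max(y), 1, tolerance = 0.05)
  t60 <- seq(0, 60 - 1 / fs, by = 1 / fs)
  mid <- seq(round(length(t60) * 0.2), round(length(t60) * 0.8))
  drift <- bandpass_ppg(sin(2 * pi * 0.05 * t60), fs)
  expect_lt(max(abs(drift[mid])), 0.1)  # > 90% attenuation in the stopband
  expect_error(bandpass_ppg(rep(0, 100), 15), "frame_rate")
  expect_error(bandpass_ppg(rep(0, 10), 30), "2 s")
})

test_that("pulse amplitude recovers sinusoid peak-to-trough within 5%", {
  fs <- 30
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  for (f in c(0.8, 1.2, 1.6)) {
    x <- -1.7 * cos(2 * pi * f * t)   # peak-to-trough 3.4
    pa <- mean_pulse_amplitude(x, fs)
    expect_false(pa$flagged)
    expect_equal(pa$amplitude, 3.4, tolerance = 0.05 * 3.4)
  }
  pa <- mean_pulse_amplitude(-cos(2 * pi * 1.2 * t), fs)
  expect_true(pa$n_pulses %in% 5:6)
})

test_that("a 5-s window yields 3-7 complete pulses at 36-84 beats/min", {
  fs <- 30
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  for (bpm in c(36, 48, 60, 72, 84)) {
    pa <- mean_pulse_amplitude(-cos(2 * pi * bpm / 60 * t), fs)
    expect_gte(pa$n_pulses, 3)
    expect_lte(pa$n_pulses, 7)
  }
})

test_that("constant and sub-prominence series are flagged as pulseless", {
  fs <- 30
  pa <- mean_pulse_amplitude(rep(0, 150), fs)
  expect_true(pa$flagged)
  expect_equal(pa$amplitude, 0)
  tiny <- 0.1 * sin(2 * pi * 1.2 * seq(0, 5, by = 1 / fs))
  expect_true(mean_pulse_amplitude(tiny, fs)$flagged)  # below 0.5 floor
})

test_that("pulse averaging matches the brute-force extremum oracle", {
  fs <- 30
  for (seed in 1:100) {
    x <- random_pulse_signal(seed, fs)
    got <- mean_pulse_amplitude(x, fs)
    want <- pulse_oracle(x, fs)
    expect_equal(got$amplitude, want$amplitude, tolerance = 1e-12)
    expect_equal(got$n_pulses, want$n_pulses)
  }
})

test_that("a session yields one oscillogram point per level, by force", {
  s <- test_subject()
  rec <- synth_session(s, seed = 14, mode = "signal")
  osc <- subject_oscillogram(rec)
  expect_s3_class(osc, "oscillogram")
  expect_equal(nrow(osc), 20)
  expect_equal(attr(osc, "n_raw"), 20)
  expect_false(attr(osc, "normalized"))
  expect_true(all(diff(osc$force_scale) > 0))
  expect_equal(osc$pressure_mmHg, pressure_from_scale(osc$force_scale))
  # determinism of the full path
  expect_identical(osc, subject_oscillogram(rec))
})

test_that("missing levels are reported as gaps", {
  rec <- synth_session(test_subject(), seed = 14, mode = "signal")
  lv <- session_levels(rec)
  broken <- lv[-7]
  attr(broken, "frame_rate") <- attr(lv, "frame_rate")
  expect_error(build_oscillogram(broken), "missing levels: 7")
})

test_that("noiseless oscillogram is unimodal with its peak at mean BP", {
  s <- test_subject(130, 85)
  rec <- synth_session(s, optics = optics_model(noise_sd = 0), seed = 2,
                       mode = "signal")
  osc <- subject_oscillogram(rec)
  spacing <- diff(osc$pressure_mmHg)
  k <- which.max(osc$amplitude)
  expect_lt(abs(osc$pressure_mmHg[k] - s$mbp_true), max(spacing))
  # unimodal: non-decreasing up to the peak, non-increasing after
  expect_true(all(diff(osc$amplitude[1:k]) >= -1e-9))
  expect_true(all(diff(osc$amplitude[k:nrow(osc)]) <= 1e-9))
  # amplitudes at pressures above SBP are flagged zero
  expect_true(all(osc$amplitude[osc$pressure_mmHg >= s$sbp_true + 15] == 0))
})

test_that("endpoint exclusion keeps 18 of 20 points, normalized to [0,1]", {
  rec <- synth_session(test_subject(), seed = 6, mode = "signal")
  osc <- subject_oscillogram(rec)
  norm <- exclude_and_normalize(osc)
  expect_equal(nrow(norm), 18)
  expect_equal(min(norm$amplitude), 0)
  expect_equal(max(norm$amplitude), 1)
  expect_true(attr(norm, "normalized"))
  expect_equal(attr(norm, "n_raw"), 20)
  # the dropped rows are the lowest and highest force levels
  expect_false(min(osc$force_scale) %in% norm$force_scale)
  expect_false(max(osc$force_scale) %in% norm$force_scale)
  md <- exclude_and_normalize(osc, method = "maxdiv")
  expect_equal(max(md$amplitude), 1)
})

test_that("a single spike normalizes to one 1 among zeros", {
  df <- data.frame(level = 1:8, force_scale = seq(10, 80, by = 10),
                   pressure_mmHg = seq(40, 250, length.out = 8),
                   amplitude = c(0, 0, 0, 5, 0, 0, 0, 0),
                   n_pulses = 4L, flagged = FALSE)
  osc <- structure(df, n_raw = 8L, normalized = FALSE,
                   class = c("oscillogram", "data.frame"))
  norm <- exclude_and_normalize(osc)
  expect_equal(sort(unique(norm$amplitude)), c(0, 1))
  expect_equal(sum(norm$amplitude == 1), 1)
  flat <- osc
  flat$amplitude <- rep(2, 8)
  expect_error(exclude_and_normalize(flat), "degenerate")
})

test_that("screening excludes pulseless and high-pulse-pressure subjects", {
  rec <- synth_session(test_subject(), seed = 6, mode = "signal")
  osc <- subject_oscillogram(rec)
  expect_true(screen_subject(osc, 120, 80)$retained)
  expect_equal(screen_subject(osc, 120, 80)$reason, "ok")
  sc <- screen_subject(osc, 170, 85)
  expect_false(sc$retained)
  expect_equal(sc$reason, "pulse_pressure_gt_80")
  dead <- osc
  dead$amplitude <- rep(0, nrow(dead))
  expect_equal(screen_subject(dead, 120, 80)$reason, "no_pulse")
})
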