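test_that("trial generation is a pure function of its arguments", {
  cfg <- quick_config()
  subj <- subject_profile("s1")
  stim <- stimulus_spec("Bitter", 0.316)
  t1 <- generate_trial(stim, subj, cfg, seed = 11)
  t2 <- generate_trial(stim, subj, cfg, seed = 11)
  expect_identical(t1$signal, t2$signal)
  t3 <- generate_trial(stim, subj, cfg, seed = 12)
  expect_false(identical(t1$signal, t3$signal))
})

test_that("an all-zero configuration yields an all-zero signal", {
  tr <- generate_trial(stimulus_spec("Salty", 2), subject_profile("s1"),
                       silent_config(), seed = 1)
  expect_equal(tr$signal, matrix(0, 6, 2000))
})

test_that("channel band power scales with the configured activation gain", {
  # carrier-only trials at full duration; channel 2, Salty intensity 5 vs 0
  cfg <- generator_config(wander_amplitude = 0, harmonic_amplitudes = 0)
  subj <- subject_profile("s1")
  hi <- generate_trial(stimulus_spec("Salty", 2), subj, cfg, seed = 5)
  lo <- generate_trial(stimulus_spec("Salty", 0), subj, cfg, seed = 6)
  p_hi <- band_power(hi$signal[2, ], 1000, 20, 450)
  p_lo <- band_power(lo$signal[2, ], 1000, 20, 450)
  gain_ratio <- channel_gain(cfg, subj, "Salty", 2, 5) /
    channel_gain(cfg, subj, "Salty", 2, 0)
  expect_equal(sqrt(p_hi / p_lo), gain_ratio, tolerance = 0.1)
})

test_that("expected per-channel RMS is nondecreasing in intensity for negative-hedonic tastes", {
  cfg <- generator_config(trial_duration = 2, wander_amplitude = 0,
                          harmonic_amplitudes = 0)
  subj <- subject_profile("s1")
  for (taste in negative_hedonic_tastes()) {
    gains <- vapply(0:5, function(i) channel_gain(cfg, subj, taste, 2, i),
                    numeric(1))
    expect_true(all(diff(gains) >= 0))
    rms <- vapply(0:5, function(i) {
      conc <- tastant_table()
      conc <- conc$concentration[conc$taste == taste &
                                   conc$strength_label == i]
      tr <- generate_trial(stimulus_spec(taste, conc), subj, cfg,
                           seed = 100 + i)
      sqrt(mean(tr$signal[2, ]^2))
    }, numeric(1))
    # carrier is normalized to exact RMS before scaling, so this is exact
    expect_equal(rms / rms[1], gains / gains[1], tolerance = 1e-10)
  }
  # positive-hedonic tastes stay flat under the default profile
  expect_equal(channel_gain(cfg, subj, "Sweet", 2, 5),
               channel_gain(cfg, subj, "Sweet", 2, 0))
})

test_that("dataset size follows subjects x sessions x tastes x intensities", {
  cfg <- quick_config()
  ds1 <- generate_dataset(subject_profile("s1"), 2, cfg)
  expect_length(ds1, 60)
  subs <- lapply(paste0("s", 1:5), subject_profile)
  ds5 <- generate_dataset(subs, 2, cfg)
  expect_length(ds5, 300)
  md <- dataset_metadata(ds5)
  expect_equal(nrow(dplyr::distinct(md, subject, session, taste,
                                    intensity_index)), 300)
})

test_that("the emitted stimuli enumerate 26 distinct solutions, counting water once", {
  md <- dataset_metadata(generate_dataset(subject_profile("s1"), 1,
                                          quick_config()))
  sol <- dplyr::distinct(md, taste, concentration)
  sol$taste[sol$concentration == 0] <- "water"
  expect_equal(nrow(dplyr::distinct(sol)), 26)
})

test_that("per-trial seeds make regeneration order-independent", {
  cfg <- quick_config(seed = 99L)
  ds <- generate_dataset(subject_profile("s1"), 1, cfg, tastes = "Sour")
  # regenerate the fourth trial alone from the same master seed
  md <- dataset_metadata(ds)
  i <- 4L
  stim <- stimulus_spec(md$taste[i], md$concentration[i])
  seed <- semgtaste:::.trial_seed(cfg$seed, 1, 1, match(md$taste[i], primary_tastes()),
                                  md$intensity_index[i])
  solo <- generate_trial(stim, subject_profile("s1"), cfg, seed = seed)
  expect_identical(solo$signal, ds[[i]]$signal)
})

test_that("baseline wander concentrates its power below 5 Hz", {
  cfg <- generator_config(trial_duration = 12, carrier_rms = 0,
                          harmonic_amplitudes = 0)
  tr <- generate_trial(stimulus_spec("Sour", 0.2), subject_profile("s1"),
                       cfg, seed = 3)
  x <- tr$signal[1, ]
  expect_gt(band_power(x, 1000, 0, 5) / band_power(x, 1000, 0, 500), 0.95)
})

test_that("a harmonics-only signal peaks exactly at multiples of 50 Hz", {
  cfg <- generator_config(trial_duration = 1, carrier_rms = 0,
                          wander_amplitude = 0,
                          harmonic_amplitudes = c(10, 5, 2))
  tr <- generate_trial(stimulus_spec("Sour", 0.2), subject_profile("s1"),
                       cfg, seed = 3)
  mag <- Mod(stats::fft(tr$signal[1, ]))[1:500]
  peaks <- which(mag > 0.01 * max(mag)) - 1  # 0-based bins = Hz
  expect_setequal(peaks, c(50, 100, 150))
})

test_that("scale scores are monotone in intensity with calibrated noise", {
  quiet <- subject_profile("s1", score_noise_sd = 0)
  expect_equal(assign_scale_score(stimulus_spec("Sour", 0), quiet, 1), 0)
  expect_equal(assign_scale_score(stimulus_spec("Sour", 0.2), quiet, 1), 10)
  expect_equal(assign_scale_score(stimulus_spec("Sour", 0.02), quiet, 1), 6)
  noisy <- subject_profile("s1", score_noise_sd = 1)
  stim <- stimulus_spec("Sour", 0.02)  # intensity 3, mean 6
  draws <- vapply(1:1000, function(s) assign_scale_score(stim, noisy, s),
                  numeric(1))
  expect_true(all(draws >= 0 & draws <= 10))
  expect_lt(abs(mean(draws) - 6), 3 * 1 / sqrt(1000))
})
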