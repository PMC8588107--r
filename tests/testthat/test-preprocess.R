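test_that("sliding-window augmentation produces the expected offsets and slices", {
  cfg <- generator_config()
  tr <- generate_trial(stimulus_spec("Sour", 0.2), subject_profile("s1"),
                       cfg, seed = 2)
  wins <- augment_windows(tr, window_s = 1, step_s = 0.25)
  expect_length(wins, 45)  # floor((12000 - 1000)/250) + 1
  offs <- vapply(wins, `[[`, integer(1), "window_offset")
  expect_equal(offs, seq(0L, 11000L, by = 250L))
  expect_true(all(offs %% 250L == 0L))
  # window contents are bit-exact slices of the trial
  w10 <- wins[[10]]
  expect_identical(w10$signal,
                   tr$signal[, (w10$window_offset + 1):(w10$window_offset + 1000)])
  # non-overlapping windows tile the trial exactly
  tiles <- augment_windows(tr, window_s = 1, step_s = 1)
  expect_identical(do.call(cbind, lapply(tiles, `[[`, "signal")), tr$signal)
})

test_that("a trial of exactly one window length yields one window; shorter warns", {
  cfg <- generator_config(trial_duration = 1)
  tr <- generate_trial(stimulus_spec("Sour", 0.2), subject_profile("s1"),
                       cfg, seed = 2)
  wins <- augment_windows(tr)
  expect_length(wins, 1)
  expect_equal(wins[[1]]$window_offset, 0L)
  short <- generate_trial(stimulus_spec("Sour", 0.2), subject_profile("s1"),
                          generator_config(trial_duration = 0.5), seed = 2)
  expect_warning(w0 <- augment_windows(short), "shorter")
  expect_length(w0, 0)
})

test_that("QVR removes constants and the lambda = 0 case exactly", {
  expect_equal(qvr(rep(3.7, 100), lambda = 2), rep(0, 100),
               ignore_attr = TRUE, tolerance = 1e-12)
  x <- rnorm(50)
  expect_equal(qvr(x, lambda = 0), rep(0, 50), ignore_attr = TRUE)
  expect_equal(attr(qvr(x, lambda = 0), "baseline"), x)
  expect_error(qvr(c(1, NA, 3), 2), "finite")
})

test_that("the tridiagonal QVR solve agrees with a dense-matrix oracle", {
  dense_qvr <- function(x, lambda) {
    n <- length(x)
    D <- diff(diag(n))  # (n-1) x n first differences
    x - solve(diag(n) + lambda * crossprod(D), x)
  }
  for (n in c(2, 16, 200)) {
    x <- withr::with_seed(n, rnorm(n))
    z <- qvr(x, lambda = 2)
    expect_equal(as.numeric(z), dense_qvr(x, 2), tolerance = 1e-10)
  }
})

test_that("QVR is linear and tends to mean removal as lambda grows", {
  x <- withr::with_seed(1, rnorm(300))
  y <- withr::with_seed(2, rnorm(300))
  lhs <- qvr(2 * x + 3 * y, 2)
  rhs <- 2 * qvr(x, 2) + 3 * qvr(y, 2)
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-10)
  # lambda -> Inf: removed baseline -> the window mean
  z <- qvr(x, 1e9)
  expect_equal(as.numeric(z), x - mean(x), tolerance = 1e-4)
})

test_that("matrix QVR treats rows as channels, matching vector calls", {
  m <- withr::with_seed(3, matrix(rnorm(400), nrow = 4))
  z <- qvr(m, 2)
  for (ch in 1:4) {
    expect_equal(z[ch, ], as.numeric(qvr(m[ch, ], 2)), tolerance = 1e-12)
  }
})

test_that("the notch attenuates a triggered 50 Hz tone by at least 20 dB", {
  t <- (0:999) / 1000
  x <- sin(2 * pi * 50 * t) + withr::with_seed(4, rnorm(1000, sd = 0.01))
  res <- adaptive_notch(tone_window(x))
  mag_before <- Mod(stats::fft(x))[51]        # 50 Hz bin
  mag_after <- Mod(stats::fft(res$window$signal[1, ]))[51]
  expect_gt(20 * log10(mag_before / mag_after), 20)
  expect_gt(res$report$removed_power_fraction[1], 0.5)
})

test_that("the notch leaves an interference-free tone untouched (adaptivity)", {
  t <- (0:999) / 1000
  x <- sin(2 * pi * 80 * t) + withr::with_seed(5, rnorm(1000, sd = 0.05))
  res <- adaptive_notch(tone_window(x))
  rel_rms <- sqrt(mean((res$window$signal[1, ] - x)^2)) / sqrt(mean(x^2))
  expect_lt(rel_rms, 0.01)
  expect_equal(res$report$n_harmonics_modified[1], 0L)
})

test_that("carrier band power survives notching of strong mains", {
  carrier <- semgtaste:::.band_limited_carrier  # unit-RMS 20-450 Hz noise
  x <- withr::with_seed(6, carrier(1000, 1000, c(20, 450)))
  t <- (0:999) / 1000
  noisy <- x + 10 * sin(2 * pi * 50 * t)  # mains at 10x carrier RMS
  res <- adaptive_notch(tone_window(noisy))
  notched_bins <- c(50:52)  # 1-based bins 50..52 = 49-51 Hz
  p_clean <- band_power(x, 1000, 20, 450, exclude_bins = notched_bins)
  p_after <- band_power(res$window$signal[1, ], 1000, 20, 450,
                        exclude_bins = notched_bins)
  expect_equal(p_after / p_clean, 1, tolerance = 0.05)
})

test_that("notching twice is nearly the same as notching once", {
  t <- (0:999) / 1000
  x <- withr::with_seed(7, rnorm(1000, sd = 0.3)) +
    5 * sin(2 * pi * 50 * t) + 2 * sin(2 * pi * 150 * t)
  once <- adaptive_notch(tone_window(x))$window$signal[1, ]
  twice <- adaptive_notch(tone_window(once))$window$signal[1, ]
  expect_lt(sqrt(mean((twice - once)^2)) / sqrt(mean(once^2)), 0.01)
})

test_that("distortion rejection thresholds the removed-power fraction", {
  keep <- tibble::tibble(channel = 1:6, removed_power_fraction = 0,
                         n_harmonics_modified = 0L)
  expect_false(reject_distorted(keep))
  bad <- keep
  bad$removed_power_fraction[3] <- 0.95
  expect_true(reject_distorted(bad))
  expect_false(reject_distorted(bad, max_removed_fraction = 0.96))
})

test_that("a constructed batch with 7 interference-heavy windows loses exactly 7", {
  t <- (0:999) / 1000
  stim <- stimulus_spec("Salty", 2)
  n_heavy <- 7
  windows <- withr::with_seed(8, lapply(1:100, function(i) {
    base <- rnorm(1000, sd = 1)
    if (i <= n_heavy) base <- base + 60 * sin(2 * pi * 50 * t)
    window_sample(base, stim)
  }))
  rejected <- vapply(windows, function(w) {
    reject_distorted(adaptive_notch(w)$report)
  }, logical(1))
  expect_equal(sum(rejected), n_heavy)
  expect_true(all(rejected[1:n_heavy]))
})
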