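#' Channel-to-muscle map of the six-channel facial montage
#'
#' Channels 1 and 6 sit on the right and left masseter (channel 1 as a
#' differential pair), channel 2 on the depressor anguli oris, channel 3 on
#' the levator labii superioris, channel 4 on the risorius, and channel 5 on
#' the procerus.
#'
#' @return Named character vector of length 6 (names `ch1`..`ch6`).
#' @export
channel_muscles <- function() {
  c(ch1 = "masseter (right)",
    ch2 = "depressor anguli oris",
    ch3 = "levator labii superioris",
    ch4 = "risorius",
    ch5 = "procerus",
    ch6 = "masseter (left)")
}

#' Configuration for the synthetic sEMG generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' a band-limited stochastic EMG carrier whose per-channel energy grows with
#' taste intensity for negative-hedonic tastes, slow large-amplitude baseline
#' wander, and additive 50 Hz mains interference with harmonics.
#'
#' Per-channel activation is `carrier_rms * (1 + slope * hedonic * intensity)`
#' where `slope` is `intensity_slope[channel]` and `hedonic` is the subject's
#' hedonic gain for the taste. The default slopes are largest on channel 2
#' (depressor anguli oris) and channel 5 (procerus), the muscles that
#' dominate facial responses to unpleasant tastes.
#'
#' @param sampling_rate Sampling frequency in Hz.
#' @param trial_duration Trial length in seconds.
#' @param channel_count Number of channels.
#' @param carrier_band Two-element band (Hz) of the stochastic EMG carrier;
#'   the upper edge must be below Nyquist.
#' @param carrier_rms Baseline carrier RMS amplitude, nominal microvolts.
#' @param intensity_slope Per-channel slope of activation vs. intensity
#'   index (length `channel_count`); must be nonnegative.
#' @param wander_amplitude Total baseline-wander amplitude (microvolts).
#' @param wander_cutoff Upper frequency bound of the wander components (Hz).
#' @param powerline_freq Mains frequency in Hz.
#' @param harmonic_amplitudes Amplitudes (microvolts) of the mains sinusoid
#'   and its harmonics, one per harmonic k = 1, 2, ...
#' @param seed Master seed used by [generate_dataset()] to derive per-trial
#'   seeds.
#' @return An object of class `semg_generator_config`.
#' @export
generator_config <- function(sampling_rate = 1000,
                             trial_duration = 12,
                             channel_count = 6,
                             carrier_band = c(20, 450),
                             carrier_rms = 20,
                             intensity_slope = c(0.10, 0.60, 0.35,
                                                 0.15, 0.50, 0.15),
                             wander_amplitude = 200,
                             wander_cutoff = 2,
                             powerline_freq = 50,
                             harmonic_amplitudes = c(30, 9, 3),
                             seed = 42L) {
  stopifnot(
    sampling_rate > 0, trial_duration > 0, channel_count >= 1,
    length(carrier_band) == 2L, carrier_band[1] < carrier_band[2],
    carrier_band[2] < sampling_rate / 2,
    carrier_rms >= 0,
    length(intensity_slope) == channel_count, all(intensity_slope >= 0),
    wander_amplitude >= 0, wander_cutoff > 0,
    powerline_freq > 0, all(harmonic_amplitudes >= 0)
  )
  structure(
    list(
      sampling_rate = sampling_rate,
      trial_duration = trial_duration,
      channel_count = channel_count,
      carrier_band = carrier_band,
      carrier_rms = carrier_rms,
      intensity_slope = intensity_slope,
      wander_amplitude = wander_amplitude,
      wander_cutoff = wander_cutoff,
      powerline_freq = powerline_freq,
      harmonic_amplitudes = harmonic_amplitudes,
      seed = as.integer(seed)
    ),
    class = "semg_generator_config"
  )
}

#' Subject profile for the generator
#'
#' `hedonic_gain` scales how strongly the subject's facial muscles respond to
#' each taste. The default gives the negative-hedonic tastes (Sour, Bitter,
#' Salty) full response and leaves Sweet and Umami flat, emulating the
#' finding that facial sEMG tracks unpleasant stimuli.
#'
#' @param subject_id Identifier (coerced to character).
#' @param hedonic_gain Named numeric vector over `primary_tastes()`,
#'   nonnegative.
#' @param score_noise_sd Standard deviation of the subject's self-report
#'   noise on the 0-10 intensity scale.
#' @return An object of class `semg_subject`.
#' @export
subject_profile <- function(subject_id,
                            hedonic_gain = c(Sour = 1, Sweet = 0, Bitter = 1,
                                             Salty = 1, Umami = 0),
                            score_noise_sd = 1) {
  stopifnot(setequal(names(hedonic_gain), primary_tastes()),
            all(hedonic_gain >= 0), score_noise_sd >= 0)
  structure(
    list(
      subject_id = as.character(subject_id),
      hedonic_gain = hedonic_gain[primary_tastes()],
      score_noise_sd = score_noise_sd
    ),
    class = "semg_subject"
  )
}

#' Per-channel activation gain for a (taste, intensity) condition
#'
#' @param config A `semg_generator_config`.
#' @param subject A `semg_subject`.
#' @param taste One of `primary_tastes()`.
#' @param channel Channel index (1-based).
#' @param intensity Intensity index 0-5.
#' @return The amplitude multiplier applied to the unit-RMS carrier of that
#'   channel (so expected channel RMS is `carrier_rms * gain`).
#' @export
channel_gain <- function(config, subject, taste, channel, intensity) {
  taste <- match.arg(taste, primary_tastes())
  stopifnot(channel >= 1, channel <= config$channel_count,
            intensity >= 0, intensity <= 5)
  1 + config$intensity_slope[channel] * subject$hedonic_gain[[taste]] * intensity
}

# Band-limited unit-RMS Gaussian carrier: white noise whose Fourier
# coefficients outside [lo, hi] Hz are zeroed, then rescaled to RMS 1.
.band_limited_carrier <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  X[freq < band[1] | freq > band[2]] <- 0+0i
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Baseline wander: random-phase sinusoids below the cutoff plus a slow ramp.
.baseline_wander <- function(n, fs, amplitude, cutoff, k = 5L) {
  if (amplitude == 0) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  freqs <- stats::runif(k, 0.05, cutoff)
  phases <- stats::runif(k, 0, 2 * pi)
  amps <- amplitude * stats::runif(k, 0.5, 1) / k
  w <- numeric(n)
  for (j in seq_len(k)) w <- w + amps[j] * sin(2 * pi * freqs[j] * t + phases[j])
  ramp <- amplitude * 0.2 * stats::runif(1, -1, 1)
  w + ramp * (t / max(t) - 0.5)
}

# Mains interference: the power-line sinusoid and its harmonics with random
# phases.
.powerline <- function(n, fs, f0, amps) {
  if (length(amps) == 0 || all(amps == 0)) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  p <- numeric(n)
  for (k in seq_along(amps)) {
    if (amps[k] == 0) next
    p <- p + amps[k] * sin(2 * pi * k * f0 * t + stats::runif(1, 0, 2 * pi))
  }
  p
}

#' Generate one synthetic sEMG trial
#'
#' Output is a pure function of its arguments: the same
#' `(stimulus, subject, config, seed)` always yields bit-identical signals.
#'
#' @param stimulus A `taste_stimulus` (see [stimulus_spec()]).
#' @param subject A `semg_subject`.
#' @param config A `semg_generator_config`.
#' @param seed Integer seed for this trial.
#' @param session Session index stored in the trial metadata.
#' @return An object of class `semg_trial`: `signal` (channel x time matrix),
#'   `stimulus`, `subject_id`, `session`, `scale_score`, `channel_muscles`.
#' @export
#' @examples
#' cfg <- generator_config()
#' subj <- subject_profile("s1")
#' trial <- generate_trial(stimulus_spec("Salty", 2), subj, cfg, seed = 1)
#' dim(trial$signal)
generate_trial <- function(stimulus, subject, config = generator_config(),
                           seed = config$seed, session = 1L) {
  stopifnot(inherits(stimulus, "taste_stimulus"),
            inherits(subject, "semg_subject"),
            inherits(config, "semg_generator_config"))
  n <- round(config$sampling_rate * config$trial_duration)
  nc <- config$channel_count
  sig <- withr::with_seed(as.integer(seed), {
    m <- matrix(0, nrow = nc, ncol = n)
    for (ch in seq_len(nc)) {
      gain <- channel_gain(config, subject, stimulus$taste, ch,
                           stimulus$intensity_index)
      carrier <- if (config$carrier_rms > 0) {
        config$carrier_rms * gain *
          .band_limited_carrier(n, config$sampling_rate, config$carrier_band)
      } else numeric(n)
      wander <- .baseline_wander(n, config$sampling_rate,
                                 config$wander_amplitude, config$wander_cutoff)
      mains <- .powerline(n, config$sampling_rate, config$powerline_freq,
                          config$harmonic_amplitudes)
      m[ch, ] <- carrier + wander + mains
    }
    m
  })
  score <- assign_scale_score(stimulus, subject, seed = as.integer(seed) + 1L)
  structure(
    list(
      signal = sig,
      fs = config$sampling_rate,
      stimulus = stimulus,
      subject_id = subject$subject_id,
      session = as.integer(session),
      scale_score = score,
      channel_muscles = channel_muscles()[seq_len(nc)]
    ),
    class = "semg_trial"
  )
}

#' @export
print.semg_trial <- function(x, ...) {
  cat(sprintf(
    "<semg_trial> subject %s session %d: %s intensity %d, %d ch x %d samples\n",
    x$subject_id, x$session, x$stimulus$taste, x$stimulus$intensity_index,
    nrow(x$signal), ncol(x$signal)))
  invisible(x)
}

#' Simulate a subject's 0-10 intensity score for a stimulus
#'
#' The mean response is linear in the intensity index (0 maps to 0, 5 maps
#' to 10); Gaussian noise with the subject's `score_noise_sd` is added and
#' the result clamped to the scale.
#'
#' @inheritParams generate_trial
#' @param seed Integer seed.
#' @return A scalar in \[0, 10\].
#' @export
assign_scale_score <- function(stimulus, subject, seed) {
  stopifnot(inherits(stimulus, "taste_stimulus"),
            inherits(subject, "semg_subject"))
  mu <- 2 * stimulus$intensity_index
  if (subject$score_noise_sd == 0) return(mu)
  raw <- withr::with_seed(as.integer(seed),
                          stats::rnorm(1, mu, subject$score_noise_sd))
  min(10, max(0, raw))
}

# Order-independent per-trial seed: a small multiplicative hash of the
# master seed and the trial coordinates, kept below 2^31.
.trial_seed <- function(master, subject_idx, session, taste_idx, intensity) {
  m <- 2147483629
  h <- as.numeric(master) %% m
  for (v in c(subject_idx, session, taste_idx, intensity)) {
    h <- (h * 69069 + v + 1) %% m
  }
  as.integer(h)
}

#' Generate a full synthetic dataset
#'
#' One trial per (subject, session, taste, intensity): each session holds the
#' 5 primary tastes at 6 intensity levels each, so a subject contributes
#' `30 * sessions_per_subject` trials. Per-trial seeds are derived from the
#' master seed by a hash of the trial coordinates, so any single trial can be
#' regenerated independently of the rest.
#'
#' @param subjects A list of `semg_subject` profiles (a single profile is
#'   accepted).
#' @param sessions_per_subject Number of sessions per subject.
#' @param config A `semg_generator_config`; `config$seed` is the master seed.
#' @param tastes Tastes to include (default all five).
#' @return A list of `semg_trial` objects, class `semg_dataset`.
#' @export
#' @examples
#' ds <- generate_dataset(subject_profile("s1"), sessions_per_subject = 1,
#'                        config = generator_config(trial_duration = 2),
#'                        tastes = "Salty")
#' length(ds)  # 6 intensities
generate_dataset <- function(subjects, sessions_per_subject = 2,
                             config = generator_config(),
                             tastes = primary_tastes()) {
  if (inherits(subjects, "semg_subject")) subjects <- list(subjects)
  stopifnot(length(subjects) >= 1L, sessions_per_subject >= 1L,
            all(vapply(subjects, inherits, logical(1), "semg_subject")))
  tastes <- match.arg(tastes, primary_tastes(), several.ok = TRUE)
  grid <- tastant_table()
  trials <- list()
  for (si in seq_along(subjects)) {
    for (sess in seq_len(sessions_per_subject)) {
      for (taste in tastes) {
        ti <- match(taste, primary_tastes())
        rows <- grid[grid$taste == taste, ]
        for (r in seq_len(nrow(rows))) {
          stim <- stimulus_spec(taste, rows$concentration[r])
          seed <- .trial_seed(config$seed, si, sess, ti, stim$intensity_index)
          trials[[length(trials) + 1L]] <-
            generate_trial(stim, subjects[[si]], config,
                           seed = seed, session = sess)
        }
      }
    }
  }
  structure(trials, class = "semg_dataset")
}

#' Trial-level metadata of a dataset
#'
#' @param dataset A `semg_dataset` (or plain list of `semg_trial`s).
#' @return A tibble with one row per trial: `trial_id`, `subject`, `session`,
#'   `taste`, `concentration`, `intensity_index`, `scale_score`.
#' @export
dataset_metadata <- function(dataset) {
  tibble::tibble(
    trial_id = seq_along(dataset),
    subject = vapply(dataset, function(t) t$subject_id, character(1)),
    session = vapply(dataset, function(t) t$session, integer(1)),
    taste = vapply(dataset, function(t) t$stimulus$taste, character(1)),
    concentration = vapply(dataset,
                           function(t) t$stimulus$concentration, numeric(1)),
    intensity_index = vapply(dataset,
                             function(t) t$stimulus$intensity_index,
                             numeric(1)),
    scale_score = vapply(dataset, function(t) t$scale_score, numeric(1))
  )
}
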