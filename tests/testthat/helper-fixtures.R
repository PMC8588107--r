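# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# The default synthetic Salty series: 1 subject, 2 sessions, 12-second
# trials, master seed 42. Processed through the full preprocessing +
# feature-extraction pipeline.
salty_features <- function() {
  if (is.null(.fixture_env$salty)) {
    ds <- generate_dataset(subject_profile("s1"), sessions_per_subject = 2,
                           config = generator_config(seed = 42),
                           tastes = "Salty")
    .fixture_env$salty <- process_dataset(ds)
  }
  .fixture_env$salty
}

# A short-trial config for structural checks where duration is irrelevant.
quick_config <- function(seed = 7L) {
  generator_config(trial_duration = 2, seed = seed)
}

# A silent generator: no carrier, no wander, no mains.
silent_config <- function(duration = 2) {
  generator_config(trial_duration = duration, carrier_rms = 0,
                   wander_amplitude = 0, harmonic_amplitudes = 0)
}

# One-channel window around a given vector signal.
tone_window <- function(x, fs = 1000, taste = "Salty", conc = 2) {
  window_sample(x, stimulus_spec(taste, conc), fs = fs)
}

# Total power of a signal within [lo, hi] Hz, excluding the given bins
# (1-based positive-frequency indices), via the periodogram.
band_power <- function(x, fs, lo, hi, exclude_bins = integer(0)) {
  n <- length(x)
  mag2 <- Mod(stats::fft(x))[seq_len(floor(n / 2))]^2
  freq <- (seq_len(floor(n / 2)) - 1) * fs / n
  keep <- freq >= lo & freq <= hi
  if (length(exclude_bins)) keep[exclude_bins] <- FALSE
  sum(mag2[keep])
}

# A synthetic feature table: n rows, all 330 feature columns filled with
# noise, plus label/metadata columns. Used for model-level fixtures.
noise_feature_table <- function(n, seed = 1, label = NULL) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 330), nrow = n)
    colnames(X) <- sprintf("f%03d", 1:330)
    lab <- label %||% sample(0:5, n, replace = TRUE)
    dplyr::bind_cols(
      tibble::tibble(
        subject = "s1", session = 1L,
        trial_id = rep(seq_len(ceiling(n / 5)), each = 5L)[seq_len(n)],
        window_offset = 0L, taste = "Salty", concentration = 2,
        intensity_index = lab, strength_label = lab,
        relative_concentration = lab / 5, scale_score = 2 * lab
      ),
      tibble::as_tibble(X)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
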