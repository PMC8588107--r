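#' One-sided magnitude spectrum of a window channel
#'
#' Unnormalized magnitude of the discrete Fourier transform, one-sided, no
#' taper: bin `i` (0-based) corresponds to frequency `i * fs / L` Hz. At the
#' default 1 s window and 1000 Hz rate the resolution is 1 Hz and the
#' spectrum covers 0-499 Hz in 500 bins.
#'
#' @param x Numeric signal of length L.
#' @param fs Sampling rate in Hz.
#' @return A list of class `channel_spectrum`: `magnitudes` (length L/2),
#'   `bin_hz` (fs/L), `freq` (bin center frequencies, Hz).
#' @export
channel_spectrum <- function(x, fs = 1000) {
  if (!all(is.finite(x))) stop("non-finite values in input signal")
  L <- length(x)
  half <- floor(L / 2)
  mag <- Mod(stats::fft(x))[seq_len(half)]
  structure(
    list(magnitudes = mag, bin_hz = fs / L,
         freq = (seq_len(half) - 1) * fs / L),
    class = "channel_spectrum"
  )
}

#' Band-power features: 50 spectral sums over 10 Hz intervals
#'
#' Band `n` sums the spectrum magnitudes over `[(n-1)*10, n*10)` Hz for
#' `n = 1..50`, a disjoint partition of 0-499 Hz (DC included in band 1), so
#' the 50 features sum exactly to the total spectral magnitude.
#'
#' @param spec A `channel_spectrum` (500 bins at the default geometry).
#' @return Numeric vector of 50 band sums.
#' @export
band_features <- function(spec) {
  stopifnot(inherits(spec, "channel_spectrum"))
  mag <- spec$magnitudes
  bins_per_band <- length(mag) / 50
  stopifnot(bins_per_band == round(bins_per_band))
  colSums(matrix(mag, nrow = bins_per_band))
}

#' Spectral moment features: frequency centroid, RMS frequency, and
#' root-variance frequency
#'
#' Treating the magnitude spectrum as a weight over bin frequencies:
#' `FC = sum(f * w) / sum(w)`, `RMSF = sqrt(sum(f^2 * w) / sum(w))`,
#' `RVF = sqrt(sum((f - FC)^2 * w) / sum(w))`, all in Hz; the identity
#' `RMSF^2 = FC^2 + RVF^2` holds by construction.
#'
#' @param spec A `channel_spectrum`.
#' @return Named numeric vector `c(FC, RMSF, RVF)`; all `NA` with a warning
#'   when the spectrum has zero total magnitude (moments undefined).
#' @export
moment_features <- function(spec) {
  stopifnot(inherits(spec, "channel_spectrum"))
  w <- spec$magnitudes
  tot <- sum(w)
  if (tot <= 0) {
    warning("all-zero spectrum: spectral moments undefined")
    return(c(FC = NA_real_, RMSF = NA_real_, RVF = NA_real_))
  }
  f <- spec$freq
  fc <- sum(w * f) / tot
  rmsf <- sqrt(sum(w * f^2) / tot)
  rvf <- sqrt(sum(w * (f - fc)^2) / tot)
  c(FC = fc, RMSF = rmsf, RVF = rvf)
}

#' Time-domain features: RMS and mean absolute value
#'
#' @param x Numeric signal.
#' @return Named numeric vector `c(RMS, MAV)`.
#' @export
time_features <- function(x) {
  stopifnot(all(is.finite(x)))
  c(RMS = sqrt(mean(x^2)), MAV = mean(abs(x)))
}

#' Extract the 55-feature set for one channel
#'
#' Features 1-50 are the 10 Hz band sums, 51 = FC, 52 = RMSF, 53 = RVF,
#' 54 = RMS, 55 = MAV.
#'
#' @param x Numeric signal (one channel of a preprocessed window).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length 55.
#' @export
channel_features <- function(x, fs = 1000) {
  spec <- channel_spectrum(x, fs)
  c(band_features(spec), moment_features(spec), time_features(x))
}

#' Extract the full 330-dimensional feature vector of a window
#'
#' Channel-major ordering: channel 1 features 1-55, then channel 2, and so
#' on; names `f001..f330`. Feature `j` belongs to channel `ceiling(j / 55)`
#' with within-channel index `((j - 1) %% 55) + 1`.
#'
#' @param window A `semg_window` (preprocessed).
#' @return Named numeric vector of length `channels * 55`.
#' @export
#' @examples
#' trial <- generate_trial(stimulus_spec("Salty", 2), subject_profile("s1"),
#'                         generator_config(), seed = 1)
#' w <- augment_windows(trial)[[1]]
#' length(extract_features(w))  # 330
extract_features <- function(window) {
  stopifnot(inherits(window, "semg_window"))
  nc <- nrow(window$signal)
  v <- unlist(lapply(seq_len(nc), function(ch) {
    channel_features(window$signal[ch, ], window$fs)
  }), use.names = FALSE)
  names(v) <- sprintf("f%03d", seq_along(v))
  v
}

#' The feature ordering contract
#'
#' @param channels Number of channels.
#' @return A tibble with one row per feature: `feature` (name), `channel`,
#'   `within_index` (1-55), `group` (1-11; consecutive blocks of five
#'   features), and `kind` (`band`, `moment`, or `time`).
#' @export
feature_ordering <- function(channels = 6) {
  j <- seq_len(channels * 55L)
  within <- (j - 1L) %% 55L + 1L
  tibble::tibble(
    feature = sprintf("f%03d", j),
    channel = (j - 1L) %/% 55L + 1L,
    within_index = within,
    group = (within - 1L) %/% 5L + 1L,
    kind = ifelse(within <= 50L, "band",
                  ifelse(within <= 53L, "moment", "time"))
  )
}

#' Build a feature table from preprocessed windows
#'
#' @param windows A list of preprocessed `semg_window`s.
#' @return A tibble, one row per window: metadata and label columns
#'   (`subject`, `session`, `trial_id`, `window_offset`, `taste`,
#'   `concentration`, `intensity_index`, `strength_label`,
#'   `relative_concentration`, `scale_score`) followed by `f001..f330`.
#' @export
feature_table <- function(windows) {
  stopifnot(length(windows) >= 1L)
  meta <- dplyr::bind_rows(lapply(windows, function(w) {
    tibble::tibble(
      subject = w$subject,
      session = w$session,
      trial_id = w$trial_id,
      window_offset = w$window_offset,
      taste = w$stimulus$taste,
      concentration = w$stimulus$concentration,
      intensity_index = w$stimulus$intensity_index,
      strength_label = strength_label(w$stimulus),
      relative_concentration = relative_concentration(w$stimulus),
      scale_score = w$scale_score
    )
  }))
  feats <- do.call(rbind, lapply(windows, extract_features))
  dplyr::bind_cols(meta, tibble::as_tibble(feats))
}

#' Names of the feature columns of a feature table
#'
#' @param features A feature table.
#' @return Character vector of the `fNNN` columns, in order.
#' @export
feature_columns <- function(features) {
  grep("^f[0-9]{3}$", names(features), value = TRUE)
}

#' Run the full pipeline from raw trials to a feature table
#'
#' Applies [preprocess_trial()] (windowing, QVR, adaptive notch, rejection)
#' to every trial and extracts the 330-dimensional feature vectors of the
#' kept windows.
#'
#' @param dataset A `semg_dataset` (list of `semg_trial`s).
#' @param lambda QVR smoothing penalty.
#' @param ... Passed on to [preprocess_trial()].
#' @return A feature table (see [feature_table()]); the number of windows
#'   cut and rejected per trial is attached as attribute `"preprocess_log"`.
#' @export
process_dataset <- function(dataset, lambda = 2, ...) {
  all_windows <- list()
  log <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    pp <- preprocess_trial(dataset[[i]], lambda = lambda, ...)
    for (w in pp$windows) {
      w$trial_id <- i
      all_windows[[length(all_windows) + 1L]] <- w
    }
    log[[i]] <- tibble::tibble(trial_id = i, n_windows = pp$n_windows,
                               n_rejected = pp$n_rejected)
  }
  out <- feature_table(all_windows)
  attr(out, "preprocess_log") <- dplyr::bind_rows(log)
  out
}
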