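#' Cut a trial into overlapping window samples
#'
#' Sliding-window augmentation: 1 s windows advanced by 0.25 s by default,
#' all channels cut identically. Offsets are left-closed sample indices and
#' the last partial window is discarded.
#'
#' @param trial A `semg_trial`.
#' @param window_s Window length in seconds.
#' @param step_s Step between window starts in seconds.
#' @param fs Sampling rate in Hz (defaults to the trial's own rate).
#' @return A list of `semg_window` objects, each holding a channel x L
#'   signal matrix, the parent `trial_id` metadata, and the 0-based
#'   `window_offset` in samples. A trial shorter than one window yields an
#'   empty list with a warning.
#' @export
#' @examples
#' trial <- generate_trial(stimulus_spec("Sour", 0.2), subject_profile("s1"),
#'                         generator_config(), seed = 1)
#' length(augment_windows(trial))  # 45
augment_windows <- function(trial, window_s = 1, step_s = 0.25,
                            fs = trial$fs %||% 1000) {
  stopifnot(inherits(trial, "semg_trial"), window_s > 0, step_s > 0)
  n <- ncol(trial$signal)
  L <- round(window_s * fs)
  step <- round(step_s * fs)
  if (n < L) {
    warning("trial shorter than one window; no samples produced")
    return(list())
  }
  offsets <- seq(0L, n - L, by = step)
  lapply(offsets, function(off) {
    structure(
      list(
        signal = trial$signal[, (off + 1L):(off + L), drop = FALSE],
        fs = fs,
        trial_id = NA_integer_,
        window_offset = as.integer(off),
        subject = trial$subject_id,
        session = trial$session,
        stimulus = trial$stimulus,
        scale_score = trial$scale_score
      ),
      class = "semg_window"
    )
  })
}

#' Remove baseline wander by quadratic variation reduction
#'
#' Subtracts a penalized-smoothness fit from the raw signal:
#' `z = x - s` where `s` solves `(I + lambda * D'D) s = x` and `D` is the
#' (n-1) x n first-difference matrix. `I + lambda * D'D` is symmetric
#' positive-definite tridiagonal, solved in linear time via a sparse
#' factorization. The estimated baseline `s` is attached as attribute
#' `"baseline"`.
#'
#' Constant signals are returned as all zeros (differences annihilate
#' constants, so the smoother reproduces them exactly), and `lambda = 0`
#' maps everything to zero.
#'
#' @param x Numeric vector, or a matrix whose **rows** are signals
#'   (channel x time, matching `semg_trial`/`semg_window` layout).
#' @param lambda Nonnegative smoothing penalty; larger values remove only
#'   slower trends. Default 2.
#' @return The baseline-removed signal, same shape as `x`, with the removed
#'   baseline in `attr(, "baseline")`.
#' @export
#' @examples
#' x <- sin(2 * pi * 50 * (0:999) / 1000) + 10  # tone + offset
#' z <- qvr(x, lambda = 2)
#' mean(z)  # offset removed
qvr <- function(x, lambda = 2) {
  stopifnot(is.numeric(x) || is.matrix(x), lambda >= 0)
  if (!all(is.finite(x))) stop("non-finite values in input signal")
  mat <- is.matrix(x)
  X <- if (mat) t(x) else matrix(x, ncol = 1L)  # signals in columns
  n <- nrow(X)
  stopifnot(n >= 2L)
  if (lambda == 0) {
    out <- x * 0
    attr(out, "baseline") <- x
    return(out)
  }
  A <- Matrix::bandSparse(
    n, n,
    k = c(0L, 1L),
    diagonals = list(1 + lambda * c(1, rep(2, n - 2), 1), rep(-lambda, n - 1)),
    symmetric = TRUE
  )
  S <- as.matrix(Matrix::solve(A, X))
  Z <- X - S
  if (mat) {
    out <- t(Z)
    attr(out, "baseline") <- t(S)
  } else {
    out <- drop(Z)
    attr(out, "baseline") <- drop(S)
  }
  out
}

#' Apply QVR to every channel of a window
#'
#' @param window A `semg_window`.
#' @param lambda Smoothing penalty, see [qvr()].
#' @return The window with baseline-removed signal.
#' @export
qvr_window <- function(window, lambda = 2) {
  stopifnot(inherits(window, "semg_window"))
  z <- qvr(window$signal, lambda)
  attr(z, "baseline") <- NULL
  window$signal <- z
  window
}

# Notch one channel in the frequency domain. Returns the filtered signal and
# the fraction of total spectral power removed.
.notch_channel <- function(x, fs, f0, harmonics_max, detect_ratio,
                           halfwidth, flank_bins) {
  n <- length(x)
  X <- stats::fft(x)
  mag <- Mod(X)
  half <- floor(n / 2)
  p_before <- sum(mag^2)
  modified <- list()
  for (k in seq_len(harmonics_max)) {
    f <- k * f0
    if (f >= fs / 2) break
    b <- round(f * n / fs) + 1L  # 1-based bin of the positive-frequency peak
    lo <- b - flank_bins[2]; hi <- b + flank_bins[2]
    left <- max(2L, lo):(b - flank_bins[1])
    right <- (b + flank_bins[1]):min(half, hi)
    med_l <- stats::median(mag[left])
    med_r <- stats::median(mag[right])
    band <- max(2L, b - halfwidth):min(half, b + halfwidth)
    if (max(mag[band]) <= detect_ratio * stats::median(c(mag[left], mag[right])))
      next
    # replace the notch band by a linear ramp between the flanking medians
    repl <- seq(med_l, med_r, length.out = length(band) + 2L)
    repl <- repl[-c(1L, length(repl))]
    mag[band] <- repl
    mirror <- n + 2L - band  # conjugate bins
    mag[mirror] <- repl
    modified[[length(modified) + 1L]] <- list(harmonic = k, bins = band - 1L)
  }
  if (length(modified) == 0) {
    return(list(signal = x, removed_power_fraction = 0, modified = modified))
  }
  Y <- complex(modulus = mag, argument = Arg(X))
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  p_after <- sum(mag^2)
  frac <- if (p_before > 0) max(0, min(1, (p_before - p_after) / p_before)) else 0
  list(signal = y, removed_power_fraction = frac, modified = modified)
}

#' Adaptive notch filter for power-line interference
#'
#' Per channel, examines the discrete spectrum at the mains frequency and its
#' integer harmonics. A harmonic is treated as interference only when its
#' peak magnitude exceeds `detect_ratio` times the median magnitude of the
#' flanking bins; triggered harmonics have the magnitudes in a narrow notch
#' band replaced by linear interpolation of the flanking medians (phases
#' kept), and the signal is rebuilt by the inverse transform. Harmonics that
#' look normal are left untouched, so clean signals pass essentially
#' unchanged.
#'
#' @param window A `semg_window` (or a plain numeric vector with `fs` given).
#' @param powerline_freq Mains frequency in Hz.
#' @param harmonics_max Highest harmonic examined (k * 50 Hz must stay below
#'   Nyquist; harmonics above it are skipped).
#' @param detect_ratio Trigger threshold relative to the flanking median.
#' @param notch_halfwidth_bins Half-width of the replaced band, in bins.
#' @param flank_bins Two integers: the flank used for the local median spans
#'   bins `peak +/- flank_bins[1] .. flank_bins[2]`.
#' @return A list with `window` (filtered; same class as input) and `report`,
#'   a tibble with one row per channel: `channel`, `removed_power_fraction`,
#'   `n_harmonics_modified`.
#' @export
adaptive_notch <- function(window, powerline_freq = 50, harmonics_max = 9,
                           detect_ratio = 5, notch_halfwidth_bins = 1,
                           flank_bins = c(3L, 8L)) {
  vec <- !inherits(window, "semg_window")
  if (vec) {
    sig <- matrix(window, nrow = 1L)
    fs <- 1000
  } else {
    sig <- window$signal
    fs <- window$fs
  }
  res <- lapply(seq_len(nrow(sig)), function(ch) {
    .notch_channel(sig[ch, ], fs, powerline_freq, harmonics_max,
                   detect_ratio, notch_halfwidth_bins, flank_bins)
  })
  out <- do.call(rbind, lapply(res, `[[`, "signal"))
  report <- tibble::tibble(
    channel = seq_len(nrow(sig)),
    removed_power_fraction = vapply(res, `[[`, numeric(1),
                                    "removed_power_fraction"),
    n_harmonics_modified = vapply(res, function(r) length(r$modified),
                                  integer(1))
  )
  if (vec) {
    list(window = drop(out), report = report)
  } else {
    window$signal <- out
    list(window = window, report = report)
  }
}

#' Decide whether a notch-filtered sample is too distorted to keep
#'
#' A sample is dropped when the notch removed more than
#' `max_removed_fraction` of the total spectral power on any channel —
#' i.e. when what remains is mostly reconstruction residue rather than EMG.
#'
#' @param report The per-channel report returned by [adaptive_notch()].
#' @param max_removed_fraction Rejection threshold on the removed power
#'   fraction.
#' @return `TRUE` if the sample should be rejected.
#' @export
reject_distorted <- function(report, max_removed_fraction = 0.8) {
  any(report$removed_power_fraction > max_removed_fraction)
}

#' Preprocess one trial end to end
#'
#' Windowing, per-channel QVR baseline removal, adaptive notch, and
#' distortion-based rejection, in that order.
#'
#' @param trial A `semg_trial`.
#' @param lambda QVR smoothing penalty.
#' @param window_s,step_s Windowing parameters, see [augment_windows()].
#' @param max_removed_fraction Rejection threshold, see [reject_distorted()].
#' @param ... Further arguments passed to [adaptive_notch()].
#' @return A list: `windows` (kept, preprocessed `semg_window`s),
#'   `n_windows` (total cut), `n_rejected`.
#' @export
preprocess_trial <- function(trial, lambda = 2, window_s = 1, step_s = 0.25,
                             max_removed_fraction = 0.8, ...) {
  wins <- augment_windows(trial, window_s, step_s)
  kept <- list()
  n_rej <- 0L
  for (w in wins) {
    w <- qvr_window(w, lambda)
    nt <- adaptive_notch(w, ...)
    if (reject_distorted(nt$report, max_removed_fraction)) {
      n_rej <- n_rej + 1L
    } else {
      kept[[length(kept) + 1L]] <- nt$window
    }
  }
  list(windows = kept, n_windows = length(wins), n_rejected = n_rej)
}
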