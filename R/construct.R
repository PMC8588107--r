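#' Construct a trial from an existing recording
#'
#' Wraps a channel x time signal matrix and its stimulus metadata in the
#' trial container the pipeline operates on; use this to feed recordings
#' that were not produced by [generate_trial()].
#'
#' @param signal Numeric channel x time matrix (microvolts).
#' @param stimulus A `taste_stimulus` (see [stimulus_spec()]).
#' @param subject_id Subject identifier.
#' @param session Session index.
#' @param scale_score Subject-reported 0-10 intensity score (optional).
#' @param fs Sampling rate in Hz.
#' @return An object of class `semg_trial`.
#' @export
as_semg_trial <- function(signal, stimulus, subject_id = "s1", session = 1L,
                          scale_score = NA_real_, fs = 1000) {
  stopifnot(is.matrix(signal), all(is.finite(signal)),
            inherits(stimulus, "taste_stimulus"), fs > 0)
  structure(
    list(
      signal = signal,
      fs = fs,
      stimulus = stimulus,
      subject_id = as.character(subject_id),
      session = as.integer(session),
      scale_score = scale_score,
      channel_muscles = channel_muscles()[seq_len(nrow(signal))]
    ),
    class = "semg_trial"
  )
}

#' Construct a window sample directly
#'
#' @param signal Numeric channel x time matrix (a vector is treated as one
#'   channel).
#' @param stimulus A `taste_stimulus`.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param session Session index.
#' @param window_offset Offset of the window within its trial, in samples.
#' @param scale_score Subject-reported score (optional).
#' @return An object of class `semg_window`.
#' @export
window_sample <- function(signal, stimulus, fs = 1000, subject_id = "s1",
                          session = 1L, window_offset = 0L,
                          scale_score = NA_real_) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  stopifnot(all(is.finite(signal)), inherits(stimulus, "taste_stimulus"))
  structure(
    list(
      signal = signal,
      fs = fs,
      trial_id = NA_integer_,
      window_offset = as.integer(window_offset),
      subject = as.character(subject_id),
      session = as.integer(session),
      stimulus = stimulus,
      scale_score = scale_score
    ),
    class = "semg_window"
  )
}
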