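#' Spectral amplitude integral of one channel of a window
#'
#' The sum of the one-sided spectrum magnitudes over the full 0-499 Hz
#' range; it equals the sum of the channel's 50 band features exactly, and
#' reflects the signal energy and hence the underlying muscle activity.
#'
#' @param window A preprocessed `semg_window`.
#' @param channel Channel index.
#' @return Nonnegative scalar.
#' @export
spectral_integral <- function(window, channel) {
  stopifnot(inherits(window, "semg_window"),
            channel >= 1, channel <= nrow(window$signal))
  sum(channel_spectrum(window$signal[channel, ], window$fs)$magnitudes)
}

#' Mean muscle-activity table over (taste, intensity, channel)
#'
#' For every taste type T, intensity I, and channel C, the mean of the
#' per-sample spectral amplitude integrals is computed; the normalized value
#' divides by the same (taste, channel) cell at intensity 0, so every
#' zero-intensity cell is exactly 1. Channel 1 (the masseter differential
#' pair) is excluded by default: channel 6, a single electrode on the other
#' masseter, represents that muscle more directly; channels 2-6 map to the
#' depressor anguli oris, levator labii superioris, risorius, procerus, and
#' masseter.
#'
#' @param features A feature table (the per-channel band features encode the
#'   spectral integrals), or a list of preprocessed `semg_window`s.
#' @param channels Channels to summarize (default 2:6).
#' @return A tibble of class `activity_table`: `taste`, `intensity`,
#'   `channel`, `muscle`, `S` (mean integral), `S_norm`, `n` (sample count).
#'   Cells with no samples are absent; `S_norm` is `NA` where the
#'   intensity-0 reference is missing or zero.
#' @export
activity_table <- function(features, channels = 2:6) {
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, logical(1), "semg_window"))) {
    features <- feature_table(features)
  }
  ord <- feature_ordering()
  rows <- lapply(channels, function(ch) {
    band_cols <- ord$feature[ord$channel == ch & ord$kind == "band"]
    integral <- rowSums(as.matrix(features[, band_cols, drop = FALSE]))
    tibble::tibble(
      taste = features$taste,
      intensity = as.integer(features$intensity_index),
      channel = ch,
      integral = integral
    )
  })
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::summarise(
    dplyr::group_by(tab, .data$taste, .data$intensity, .data$channel),
    S = mean(.data$integral), n = dplyr::n(), .groups = "drop"
  )
  ref <- dplyr::select(tab[tab$intensity == 0L, ],
                       "taste", "channel", S0 = "S")
  tab <- dplyr::left_join(tab, ref, by = c("taste", "channel"))
  tab$S_norm <- ifelse(!is.na(tab$S0) & tab$S0 > 0, tab$S / tab$S0, NA_real_)
  tab$S0 <- NULL
  tab$muscle <- unname(channel_muscles()[tab$channel])
  out <- tab[order(match(tab$taste, primary_tastes()),
                   tab$intensity, tab$channel),
             c("taste", "intensity", "channel", "muscle", "S", "S_norm", "n")]
  class(out) <- c("activity_table", class(out))
  out
}

#' Heatmap of normalized muscle activity
#'
#' Linear mapping of normalized activity onto a sequential light-to-dark
#' colour scale: darker cells mean stronger activity relative to the
#' deionized-water baseline.
#'
#' @param table An `activity_table`.
#' @return A ggplot object, one panel per taste: intensity on the x axis,
#'   muscle on the y axis, fill = normalized activity.
#' @export
activity_heatmap <- function(table) {
  stopifnot(inherits(table, "activity_table"))
  ggplot2::ggplot(table, ggplot2::aes(x = factor(.data$intensity),
                                      y = .data$muscle,
                                      fill = .data$S_norm)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~ taste) +
    ggplot2::scale_fill_gradient(low = "#fff5eb", high = "#7f2704",
                                 name = "activity\n(normalized)") +
    ggplot2::labs(x = "taste intensity index", y = NULL) +
    ggplot2::theme_minimal()
}
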