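#' Greedy grouped forward selection for one channel
#'
#' The 55 features of a channel are divided into 11 consecutive groups of
#' five. Starting from an empty set, the group whose addition maximizes the
#' cross-validated mean R2 of the current set is added at each step (ties
#' broken by the lowest group index), until all 11 groups are in. The
#' resulting curve of R2 against the number of features NF (5, 10, ..., 55)
#' is summarized by its inflection point (see [inflection_point()]).
#'
#' A full channel run performs 11 + 10 + ... + 1 = 66 cross-validated fits.
#'
#' @param features A feature table.
#' @param channel Channel index 1-6.
#' @param label_column Label to regress on.
#' @param cv A [cv_spec()].
#' @param tolerance Inflection-point tolerance on R2.
#' @return An object of class `selection_trace`: `channel`, `order_added`
#'   (group indices in addition order), `curve` (tibble NF, R2),
#'   `inflection_NF`, `reserved_groups`, `reserved_features`.
#' @export
greedy_channel_selection <- function(features, channel,
                                     label_column = "strength_label",
                                     cv = cv_spec(), tolerance = 0.02) {
  ord <- feature_ordering(channels = max(channel, 6))
  ord <- ord[ord$channel == channel, ]
  stopifnot(nrow(ord) == 55L)
  groups <- split(ord$feature, ord$group)
  remaining <- seq_along(groups)
  chosen <- integer(0)
  curve <- vector("list", length(groups))
  for (step in seq_along(groups)) {
    best_r2 <- -Inf
    best_g <- NA_integer_
    for (g in remaining) {
      cols <- unlist(groups[c(chosen, g)], use.names = FALSE)
      r2 <- fit_cv(features, label_column, cv, columns = cols)$mean_r2
      if (r2 > best_r2 + 1e-12) {  # strict improvement; first (lowest) wins ties
        best_r2 <- r2
        best_g <- g
      }
    }
    chosen <- c(chosen, best_g)
    remaining <- setdiff(remaining, best_g)
    curve[[step]] <- tibble::tibble(NF = 5L * step, R2 = best_r2)
  }
  curve <- dplyr::bind_rows(curve)
  infl <- inflection_point(curve, tolerance)
  reserved <- chosen[seq_len(infl %/% 5L)]
  structure(
    list(
      channel = channel,
      order_added = chosen,
      curve = curve,
      inflection_NF = infl,
      reserved_groups = sort(reserved),
      reserved_features = unlist(groups[sort(reserved)], use.names = FALSE)
    ),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> channel %d: inflection at NF = %d\n",
              x$channel, x$inflection_NF))
  cat(sprintf("  groups in order added: %s\n",
              paste(x$order_added, collapse = " ")))
  invisible(x)
}

#' Inflection point of an R2-vs-NF selection curve
#'
#' Among all points whose R2 is within `tolerance` of the curve maximum, the
#' one with the largest NF is chosen: beyond it, adding features degrades
#' the model by more than the tolerance allows.
#'
#' @param curve A tibble/data frame with columns `NF` and `R2`.
#' @param tolerance Allowed drop below the maximum R2.
#' @return The NF value of the inflection point.
#' @export
#' @examples
#' curve <- data.frame(NF = seq(5, 55, 5),
#'                     R2 = c(0.22, 0.24, 0.25, 0.2642, 0.2591,
#'                            0.24, 0.23, 0.23, 0.22, 0.22, 0.21))
#' inflection_point(curve)  # 25
inflection_point <- function(curve, tolerance = 0.02) {
  stopifnot(nrow(curve) >= 1L, all(c("NF", "R2") %in% names(curve)))
  ok <- curve$R2 >= max(curve$R2) - tolerance
  max(curve$NF[ok])
}

#' Combine per-channel selections and refit on the reduced set
#'
#' The reduced feature set is the union, over channels, of the groups each
#' channel added up to its inflection point; its dimensionality is the sum
#' of the per-channel inflection NFs. The model is refit by cross-validation
#' on the reduced set.
#'
#' @param traces A list of `selection_trace`s, one per channel.
#' @param features The full feature table.
#' @param label_column Label to regress on.
#' @param cv A [cv_spec()].
#' @return A list: `columns` (reduced feature names), `dimensionality`,
#'   `per_channel_NF`, `cv` (the `semg_cv` refit on the reduced set).
#' @export
combine_channels <- function(traces, features,
                             label_column = "strength_label",
                             cv = cv_spec()) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "selection_trace")))
  cols <- unlist(lapply(traces, `[[`, "reserved_features"), use.names = FALSE)
  nf <- vapply(traces, `[[`, numeric(1), "inflection_NF")
  stopifnot(length(cols) == sum(nf))
  list(
    columns = cols,
    dimensionality = length(cols),
    per_channel_NF = nf,
    cv = fit_cv(features, label_column, cv, columns = cols)
  )
}

#' Run channel-wise selection over all channels and recombine
#'
#' @param features A feature table.
#' @param label_column Label to regress on.
#' @param cv A [cv_spec()].
#' @param channels Channels to select over.
#' @param tolerance Inflection tolerance.
#' @return A list: `traces` (per channel), `reduced` (see
#'   [combine_channels()]), `full_cv` (CV on all 330 features, for
#'   comparison).
#' @export
select_features <- function(features, label_column = "strength_label",
                            cv = cv_spec(), channels = 1:6,
                            tolerance = 0.02) {
  traces <- lapply(channels, function(ch) {
    greedy_channel_selection(features, ch, label_column, cv, tolerance)
  })
  list(
    traces = traces,
    reduced = combine_channels(traces, features, label_column, cv),
    full_cv = fit_cv(features, label_column, cv)
  )
}

#' Plot an R2-vs-NF selection curve
#'
#' @param trace A `selection_trace` (or list of them).
#' @return A ggplot object with the curve(s) and the chosen inflection
#'   point(s) circled.
#' @export
plot_selection_curve <- function(trace) {
  if (inherits(trace, "selection_trace")) trace <- list(trace)
  df <- dplyr::bind_rows(lapply(trace, function(tr) {
    dplyr::mutate(tr$curve, channel = factor(tr$channel),
                  inflection = .data$NF == tr$inflection_NF)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$NF, y = .data$R2,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[df$inflection, ], shape = 21, size = 4,
                        stroke = 1.2, fill = NA, colour = "red") +
    ggplot2::scale_x_continuous(breaks = seq(5, 55, 10)) +
    ggplot2::labs(x = "number of features (NF)",
                  y = expression(R^2 ~ "(5-fold CV)")) +
    ggplot2::theme_minimal()
}
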