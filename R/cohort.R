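#' All nonempty subject combinations
#'
#' For a pool of five subjects this yields 31 subsets (5 singletons, 10
#' pairs, 10 triples, 5 quadruples, and the full pool), ordered by size and
#' then lexicographically.
#'
#' @param pool Character vector of subject identifiers.
#' @return A list of character vectors.
#' @export
#' @examples
#' length(subject_combinations(paste0("s", 1:5)))  # 31
subject_combinations <- function(pool) {
  stopifnot(length(pool) >= 1L, !anyDuplicated(pool))
  pool <- sort(as.character(pool))
  out <- list()
  for (k in seq_along(pool)) {
    combos <- utils::combn(pool, k, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Model performance as a function of pooled-subject count
#'
#' For every nonempty subject subset, fits the cross-validated SVR on the
#' subset's pooled samples; for each subset size NS, the mean of the
#' subsets' mean R2 scores is reported as R2_NS. With heterogeneous
#' subjects, pooling more of them typically lowers R2_NS.
#'
#' @param features A feature table with a `subject` column (usually
#'   restricted to one taste type).
#' @param label_column Label to regress on.
#' @param cv A [cv_spec()].
#' @param columns Feature columns to use (e.g. a reduced set from
#'   [select_features()]); default all.
#' @return A list: `per_combination` (tibble: `subjects`, `NS`, `r2`) and
#'   `curve` (tibble: `NS`, `R2_NS`, `n_combinations`).
#' @export
r2_ns_curve <- function(features, label_column = "strength_label",
                        cv = cv_spec(), columns = NULL) {
  stopifnot("subject" %in% names(features))
  combos <- subject_combinations(unique(features$subject))
  per <- lapply(combos, function(cc) {
    sub <- features[features$subject %in% cc, , drop = FALSE]
    tibble::tibble(
      subjects = paste(cc, collapse = "+"),
      NS = length(cc),
      r2 = fit_cv(sub, label_column, cv, columns = columns)$mean_r2
    )
  })
  per <- dplyr::bind_rows(per)
  curve <- dplyr::summarise(dplyr::group_by(per, .data$NS),
                            R2_NS = mean(.data$r2),
                            n_combinations = dplyr::n(), .groups = "drop")
  list(per_combination = per, curve = curve)
}

#' Plot the R2_NS-vs-NS curve
#'
#' @param curve The `curve` tibble from [r2_ns_curve()] (or its full result
#'   list).
#' @return A ggplot object.
#' @export
plot_r2_ns <- function(curve) {
  if (is.list(curve) && !is.data.frame(curve) && !is.null(curve$curve)) {
    curve <- curve$curve
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$NS, y = .data$R2_NS)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of pooled subjects (NS)",
                  y = expression(R[NS]^2)) +
    ggplot2::theme_minimal()
}
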