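#' Tastant concentration series for the five primary tastes
#'
#' The experimental design presents each primary taste as a six-step dilution
#' series: the series maximum carries strength label 5, each half-order-of-
#' magnitude dilution drops the label by 1, and deionized water (0 mol/L) is
#' label 0. The printed concentrations are rounded (0.316 is 10^-0.5), so
#' matching is done with a small relative tolerance.
#'
#' @return A tibble with columns `taste`, `tastant`, `strength_label` (0-5)
#'   and `concentration` (mol/L), 30 rows (5 tastes x 6 levels).
#' @export
#' @examples
#' tastant_table()
tastant_table <- function() {
  tibble::tibble(
    taste = rep(primary_tastes(), each = 6L),
    tastant = rep(
      c("citric acid", "sucrose", "magnesium chloride",
        "sodium chloride", "sodium glutamate"),
      each = 6L
    ),
    strength_label = rep(5:0, times = 5L),
    concentration = c(
      0.200, 0.063, 0.020, 0.006, 0.002, 0,   # Sour
      1.000, 0.316, 0.100, 0.032, 0.010, 0,   # Sweet
      1.000, 0.316, 0.100, 0.032, 0.010, 0,   # Bitter
      2.000, 0.632, 0.200, 0.063, 0.020, 0,   # Salty
      1.000, 0.316, 0.100, 0.032, 0.010, 0    # Umami
    )
  )
}

#' The five primary tastes, in the fixed study order
#'
#' @return Character vector `c("Sour", "Sweet", "Bitter", "Salty", "Umami")`.
#' @export
primary_tastes <- function() {
  c("Sour", "Sweet", "Bitter", "Salty", "Umami")
}

#' Tastes carrying negative hedonic value
#'
#' Facial muscle responses are driven mainly by unpleasant tastes; Sweet and
#' Umami typically evoke little facial activity.
#'
#' @return Character vector of the negative-hedonic tastes.
#' @export
negative_hedonic_tastes <- function() {
  c("Sour", "Bitter", "Salty")
}

# Relative tolerance for matching a concentration against the printed grid.
.conc_tol <- 1e-6

# Locate a (taste, concentration) pair on the dilution grid; errors if the
# concentration is not (within tolerance) one of the six listed values.
.match_tastant_row <- function(taste, concentration) {
  taste <- match.arg(taste, primary_tastes())
  stopifnot(is.numeric(concentration), length(concentration) == 1L,
            is.finite(concentration), concentration >= 0)
  grid <- tastant_table()
  grid <- grid[grid$taste == taste, ]
  if (concentration == 0) return(grid[grid$concentration == 0, ])
  rel <- abs(grid$concentration - concentration) /
    pmax(grid$concentration, .Machine$double.xmin)
  hit <- which(rel <= .conc_tol)
  if (length(hit) != 1L) {
    stop(sprintf(
      "concentration %g mol/L is not in the %s series (%s)",
      concentration, taste,
      paste(format(grid$concentration), collapse = ", ")
    ), call. = FALSE)
  }
  grid[hit, ]
}

#' Define a taste stimulus
#'
#' A stimulus is a primary taste plus one of the six concentrations in that
#' taste's dilution series (including 0 mol/L, deionized water). The integer
#' intensity index (0-5) is derived from the series position.
#'
#' @param taste One of `primary_tastes()`.
#' @param concentration Tastant concentration in mol/L; must lie on the
#'   taste's dilution grid (relative tolerance 1e-6).
#' @return An object of class `taste_stimulus`: a list with `taste`,
#'   `tastant`, `concentration`, and `intensity_index`.
#' @export
#' @examples
#' stimulus_spec("Sour", 0.02)
stimulus_spec <- function(taste, concentration) {
  row <- .match_tastant_row(taste, concentration)
  structure(
    list(
      taste = row$taste,
      tastant = row$tastant,
      concentration = row$concentration,
      intensity_index = row$strength_label
    ),
    class = "taste_stimulus"
  )
}

#' @export
print.taste_stimulus <- function(x, ...) {
  cat(sprintf("<taste_stimulus> %s (%s), %g mol/L, intensity %d\n",
              x$taste, x$tastant, x$concentration, x$intensity_index))
  invisible(x)
}

#' Strength label of a stimulus
#'
#' The exponential labeling scheme: 5 at the series maximum, minus 1 per
#' half-order-of-magnitude dilution, 0 for deionized water.
#'
#' @param stimulus A `taste_stimulus`, or a taste name (with `concentration`).
#' @param concentration Concentration in mol/L when `stimulus` is a taste name.
#' @return Integer 0-5.
#' @export
#' @examples
#' strength_label("Sour", 0.02)  # 3
#' strength_label(stimulus_spec("Salty", 2))  # 5
strength_label <- function(stimulus, concentration = NULL) {
  if (inherits(stimulus, "taste_stimulus")) return(stimulus$intensity_index)
  .match_tastant_row(stimulus, concentration)$strength_label
}

#' Relative concentration of a stimulus
#'
#' The linear labeling scheme: concentration divided by the taste's series
#' maximum, so the maximum maps to 1 and water to 0.
#'
#' @inheritParams strength_label
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' relative_concentration("Sour", 0.02)  # 0.1
relative_concentration <- function(stimulus, concentration = NULL) {
  if (inherits(stimulus, "taste_stimulus")) {
    taste <- stimulus$taste
    concentration <- stimulus$concentration
  } else {
    taste <- stimulus
  }
  row <- .match_tastant_row(taste, concentration)
  grid <- tastant_table()
  cmax <- max(grid$concentration[grid$taste == row$taste])
  row$concentration / cmax
}

#' Attach the three intensity label schemes to a stimulus
#'
#' @param stimulus A `taste_stimulus`.
#' @param scale_score Optional subject-reported 0-10 intensity score.
#' @return A one-row tibble with `strength_label`, `relative_concentration`,
#'   and `scale_score` (NA when not supplied).
#' @export
label_set <- function(stimulus, scale_score = NA_real_) {
  stopifnot(inherits(stimulus, "taste_stimulus"))
  if (!is.na(scale_score)) {
    stopifnot(scale_score >= 0, scale_score <= 10)
  }
  tibble::tibble(
    strength_label = strength_label(stimulus),
    relative_concentration = relative_concentration(stimulus),
    scale_score = as.numeric(scale_score)
  )
}
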