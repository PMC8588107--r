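`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-local counter of SVR fits, used to audit how many model fits a
# selection or cohort procedure performed.
.fit_env <- new.env(parent = emptyenv())
.fit_env$count <- 0L

#' Reset the model-fit counter
#'
#' The package counts every cross-validated SVR fit performed by [fit_cv()].
#' Procedures such as greedy selection (66 fits per channel) and cohort
#' analysis (31 fits for a five-subject pool) have an exact expected fit
#' count; the counter lets users audit it.
#'
#' @return Invisibly, the counter value before the reset.
#' @export
reset_fit_counter <- function() {
  old <- .fit_env$count
  .fit_env$count <- 0L
  invisible(old)
}

#' Read the model-fit counter
#'
#' @return Number of [fit_cv()] calls since the last [reset_fit_counter()].
#' @export
get_fit_counter <- function() .fit_env$count

.bump_fit_counter <- function() .fit_env$count <- .fit_env$count + 1L
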