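#' Coefficient of determination
#'
#' `R2 = 1 - sum((yhat - y)^2) / sum((mean(y) - y)^2)`. 1 means error-free
#' prediction, 0 means no better than predicting the mean; the value is
#' unbounded below.
#'
#' @param y_true Observed values (length >= 2, not constant).
#' @param y_pred Predicted values, same length.
#' @return Scalar in (-Inf, 1].
#' @export
#' @examples
#' r2_score(c(0, 1, 2), c(0, 0, 0))  # -1.5
r2_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2,
            all(is.finite(y_true)), all(is.finite(y_pred)))
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R2 undefined: y_true is constant")
  1 - sum((y_pred - y_true)^2) / ss_tot
}

#' Cross-validation and SVR hyperparameter specification
#'
#' The regressor is epsilon-SVR with a radial-basis kernel. Features are
#' standardized per training fold (locations/scales estimated on the
#' training folds only, applied to the held-out fold), after which the
#' default kernel width `gamma = 1/d` matches the common `1/(d * var)`
#' heuristic since the standardized variance is ~1.
#'
#' @param folds Number of CV folds.
#' @param grouping `"sample"` shuffles individual windows into folds;
#'   `"trial"` keeps all windows of one trial in the same fold (overlapping
#'   windows make sample-level CV optimistic; both modes are available).
#' @param cost SVR cost parameter C.
#' @param epsilon SVR epsilon-tube width.
#' @param gamma RBF kernel width; `NULL` means `1/d`.
#' @param seed Seed for the fold shuffle.
#' @return A list of class `cv_spec`.
#' @export
cv_spec <- function(folds = 5, grouping = c("sample", "trial"),
                    cost = 1, epsilon = 0.1, gamma = NULL, seed = 42L) {
  grouping <- match.arg(grouping)
  stopifnot(folds >= 2, cost > 0, epsilon >= 0)
  structure(
    list(folds = as.integer(folds), grouping = grouping, cost = cost,
         epsilon = epsilon, gamma = gamma, seed = as.integer(seed)),
    class = "cv_spec"
  )
}

# Shuffle units (samples or trials) into folds of near-equal size.
.fold_assignment <- function(features, cv) {
  n <- nrow(features)
  if (cv$grouping == "trial" && "trial_id" %in% names(features)) {
    units <- unique(features$trial_id)
    perm <- withr::with_seed(cv$seed, sample(units))
    fold_of_unit <- stats::setNames(
      rep(seq_len(cv$folds), length.out = length(perm)), perm)
    as.integer(fold_of_unit[as.character(features$trial_id)])
  } else {
    perm <- withr::with_seed(cv$seed, sample(n))
    fold <- integer(n)
    fold[perm] <- rep(seq_len(cv$folds), length.out = n)
    fold
  }
}

#' Fit an RBF-kernel epsilon-SVR under k-fold cross-validation
#'
#' For each fold: standardize features on the training folds, fit the SVR,
#' predict the held-out fold, and score with [r2_score()]. Constant feature
#' columns are dropped with a warning. Deterministic given the data and the
#' spec's seed.
#'
#' @param features A feature table (see [feature_table()]).
#' @param label_column Name of the label column to regress on
#'   (`"strength_label"`, `"relative_concentration"`, or `"scale_score"`).
#' @param cv A [cv_spec()].
#' @param columns Feature columns to use; defaults to all `fNNN` columns.
#' @return An object of class `semg_cv`: `fold_scores`, `mean_r2`,
#'   `fold_assignment`, `predictions` (tibble of y/yhat/fold),
#'   `model_params`, `dropped_columns`.
#' @export
fit_cv <- function(features, label_column = "strength_label",
                   cv = cv_spec(), columns = NULL) {
  stopifnot(inherits(cv, "cv_spec"), label_column %in% names(features))
  columns <- columns %||% feature_columns(features)
  stopifnot(length(columns) >= 1L, all(columns %in% names(features)))
  y <- features[[label_column]]
  if (length(unique(y)) < 2) stop("label column is constant")
  if (nrow(features) < cv$folds) stop("fewer samples than folds")
  X <- as.matrix(features[, columns, drop = FALSE])
  const <- apply(X, 2, function(col) stats::sd(col) < 1e-12)
  if (any(const)) {
    warning(sprintf("dropping %d constant feature column(s)", sum(const)))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no non-constant feature columns")
  gamma <- cv$gamma %||% (1 / ncol(X))
  fold <- .fold_assignment(features, cv)
  preds <- numeric(nrow(X))
  scores <- numeric(cv$folds)
  for (k in seq_len(cv$folds)) {
    tr <- fold != k
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv < 1e-12] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- e1071::svm(x = Xtr, y = y[tr], type = "eps-regression",
                      kernel = "radial", cost = cv$cost,
                      epsilon = cv$epsilon, gamma = gamma, scale = FALSE)
    yhat <- as.numeric(stats::predict(fit, Xte))
    preds[!tr] <- yhat
    scores[k] <- r2_score(y[!tr], yhat)
  }
  .bump_fit_counter()
  structure(
    list(
      fold_scores = scores,
      mean_r2 = mean(scores),
      fold_assignment = fold,
      predictions = tibble::tibble(y = y, y_pred = preds, fold = fold),
      model_params = list(cost = cv$cost, epsilon = cv$epsilon,
                          gamma = gamma, folds = cv$folds,
                          grouping = cv$grouping, seed = cv$seed),
      dropped_columns = if (any(const)) columns[const] else character(0),
      n = nrow(X)
    ),
    class = "semg_cv"
  )
}

#' @export
print.semg_cv <- function(x, ...) {
  cat(sprintf("<semg_cv> %d-fold %s-grouped CV on %d samples\n",
              x$model_params$folds, x$model_params$grouping, x$n))
  cat(sprintf("  fold R2: %s\n",
              paste(sprintf("%.3f", x$fold_scores), collapse = " ")))
  cat(sprintf("  mean R2: %.4f\n", x$mean_r2))
  invisible(x)
}
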