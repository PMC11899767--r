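# Evaluation metrics for trait prediction: MSE, MAE, Pearson correlation
# and classification accuracy.

check_pair <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) {
    stop("metric: observed and predicted vectors differ in length (",
         length(y_obs), " vs ", length(y_pred), ")")
  }
  if (length(y_obs) == 0L) stop("metric: empty input")
}

#' Mean squared error
#'
#' `(1/N) * sum((y_pred - y_obs)^2)`; zero exactly when the prediction is
#' perfect.
#'
#' @param y_obs,y_pred Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
mse <- function(y_obs, y_pred) {
  check_pair(y_obs, y_pred)
  mean((y_pred - y_obs)^2)
}

#' Mean absolute error
#'
#' `(1/N) * sum(|y_pred - y_obs|)`; less sensitive to outliers than the
#' MSE and bounded above by `sqrt(mse)`.
#'
#' @inheritParams mse
#' @return Non-negative scalar.
#' @export
mae <- function(y_obs, y_pred) {
  check_pair(y_obs, y_pred)
  mean(abs(y_pred - y_obs))
}

#' Pearson correlation between observed and predicted values
#'
#' Covariance over the product of standard deviations, in `[-1, 1]`.
#' Requires at least two points and non-constant vectors.
#'
#' @inheritParams mse
#' @return Scalar in `[-1, 1]`.
#' @export
pcc <- function(y_obs, y_pred) {
  check_pair(y_obs, y_pred)
  if (length(y_obs) < 2L) stop("pcc(): need at least 2 samples")
  if (stats::sd(y_obs) == 0 || stats::sd(y_pred) == 0) {
    stop("pcc(): undefined for a constant vector (zero denominator)")
  }
  stats::cor(y_obs, y_pred)
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`. For more than two classes use
#' [classification_accuracy()], the same proportion-correct statistic
#' computed directly from labels.
#'
#' @param counts Named list or vector with non-negative `TP`, `TN`, `FP`,
#'   `FN`.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  counts <- as.list(counts)
  vals <- c(counts$TP, counts$TN, counts$FP, counts$FN)
  stopifnot(length(vals) == 4L, all(vals >= 0))
  total <- sum(vals)
  if (total == 0) stop("accuracy(): zero total count")
  (counts$TP + counts$TN) / total
}

#' Proportion of correctly classified samples
#'
#' Multi-class generalization of [accuracy()]: correct / total.
#'
#' @param y_obs,y_pred Label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
classification_accuracy <- function(y_obs, y_pred) {
  check_pair(y_obs, y_pred)
  mean(as.character(y_obs) == as.character(y_pred))
}

#' Confusion counts for a binary labelling
#'
#' @param y_obs,y_pred Label vectors.
#' @param positive The label treated as positive.
#' @return Named list `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_obs, y_pred, positive) {
  check_pair(y_obs, y_pred)
  po <- as.character(y_obs) == positive
  pp <- as.character(y_pred) == positive
  list(
    TP = sum(po & pp), TN = sum(!po & !pp),
    FP = sum(!po & pp), FN = sum(po & !pp)
  )
}
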