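#' Root-mean-squared error
#'
#' `sqrt(mean((y_true - y_pred)^2))`, the deviation measure reported for
#' every calibration model.
#'
#' @param y_true,y_pred numeric vectors of equal, nonzero length.
#' @return non-negative scalar.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0)
    stop("y_true and y_pred must have equal nonzero length")
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' `1 - SSres/SStot`. Equals 1 for perfect prediction and 0 for predicting
#' the mean; out-of-sample values can be negative when a model predicts
#' worse than the mean (as overfitted least squares does on high-dimensional
#' profiles).
#'
#' @param y_true observed values (must not be constant).
#' @param y_pred predictions.
#' @return scalar `<= 1`.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0)
    stop("y_true and y_pred must have equal nonzero length")
  sstot <- sum((y_true - mean(y_true))^2)
  if (sstot == 0) stop("y_true is constant; R^2 undefined")
  1 - sum((y_true - y_pred)^2) / sstot
}
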