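#' Average cell-specific productivity
#'
#' Computes the average antibody productivity per cell and day,
#' \deqn{Q_P = \frac{1}{N} \sum_{n=1}^{N}
#'   \frac{IgG_n - IgG_{n-1}}{((VCD_{n-1} + VCD_n)/2)\,\Delta t} \times 1000,}
#' where titers are in g/L, viable cell densities in 1e6 cells/mL and
#' \eqn{\Delta t} in days; the factor 1000 converts the ratio to
#' pg/(cell day).  For a full 13-day run \eqn{N = 12}; any \eqn{N \ge 1}
#' is accepted so the statistic can be evaluated as a running mean up to an
#' arbitrary process day.
#'
#' @param titers Numeric vector of daily titers \eqn{IgG_0..IgG_N}, g/L.
#' @param vcds Numeric vector of daily viable cell densities, 1e6 cells/mL,
#'   same length as \code{titers}.
#' @param dt Sampling interval in days (default 1).
#'
#' @return Mean specific productivity in pg/(cell day).
#' @examples
#' qp_mean(titers = seq(0, 0.24, by = 0.02), vcds = rep(1, 13))  # 20
#' @export
qp_mean <- function(titers, vcds, dt = 1) {
  if (length(titers) != length(vcds)) stop_choopt("qp_mean: titers and vcds differ in length")
  if (length(titers) < 2L) stop_choopt("qp_mean: need at least two samples")
  if (!is_number(dt) || dt <= 0) stop_choopt("qp_mean: dt must be > 0")
  avg_vcd <- (vcds[-length(vcds)] + vcds[-1L]) / 2
  if (any(!is.finite(avg_vcd)) || any(avg_vcd <= 0)) {
    stop_choopt("qp_mean: averaged VCD must be positive for every interval")
  }
  inc <- diff(titers)
  mean(inc * 1000 / (avg_vcd * dt))
}

#' L2-regularized mean squared error
#'
#' The training loss of the surrogate networks,
#' \deqn{L = \frac{1}{2n} \sum_i \|\hat y_i - y_i\|^2 +
#'   \frac{\alpha}{2n} \|W\|^2,}
#' reported here as a standalone audit metric.  \code{y_true}/\code{y_pred}
#' may be vectors or matrices (rows = samples); \code{weight_norm_sq} is the
#' squared L2 norm of the model's weights.
#'
#' @param y_true,y_pred Observed and predicted values (equal dimensions).
#' @param alpha Non-negative regularization weight.
#' @param weight_norm_sq Squared L2 norm of the penalized coefficients.
#'
#' @return The scalar loss.
#' @examples
#' loss_mse_l2(c(0, 2), c(0, 0))                                   # 1.0
#' loss_mse_l2(c(0, 2), c(0, 0), alpha = 0.1, weight_norm_sq = 2)  # 1.05
#' @export
loss_mse_l2 <- function(y_true, y_pred, alpha = 0, weight_norm_sq = 0) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop_choopt("loss_mse_l2: dimension mismatch")
  n <- nrow(y_true)
  if (n == 0L) stop_choopt("loss_mse_l2: no samples")
  if (!is_number(alpha) || alpha < 0) stop_choopt("loss_mse_l2: alpha must be >= 0")
  if (!is_number(weight_norm_sq) || weight_norm_sq < 0) {
    stop_choopt("loss_mse_l2: weight_norm_sq must be >= 0")
  }
  sum((y_pred - y_true)^2) / (2 * n) + alpha * weight_norm_sq / (2 * n)
}

#' Coefficient of determination
#'
#' \deqn{R^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2.}
#' The best possible value is 1; a model predicting the mean scores 0, and
#' arbitrarily poor models score negative.  For matrix input the scores per
#' column are averaged uniformly (the multi-output convention used
#' throughout the package).
#'
#' @param y_true Observed values (vector or matrix, rows = samples).
#' @param y_pred Predicted values, same dimensions.
#'
#' @return The (uniformly averaged) R-squared.
#' @examples
#' r2_score(c(1, 2, 3), c(1, 2, 2))  # 0.5
#' @export
r2_score <- function(y_true, y_pred) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) stop_choopt("r2_score: dimension mismatch")
  if (nrow(y_true) < 2L) stop_choopt("r2_score: need at least two samples")
  ss_tot <- colSums(sweep(y_true, 2, colMeans(y_true))^2)
  if (any(ss_tot == 0)) {
    stop_choopt("r2_score: y_true column %s is constant, denominator is zero",
                paste(which(ss_tot == 0), collapse = ","))
  }
  ss_res <- colSums((y_true - y_pred)^2)
  mean(1 - ss_res / ss_tot)
}
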