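#' Relative Prediction Error (RPE)
#'
#' The held-out goodness-of-fit statistic: the square root of the mean
#' squared prediction error at the evaluation points, divided by the range of
#' the *predicted* responses there, expressed as a percentage:
#'
#' \deqn{RPE = 100 \sqrt{\sum_j (y_j - f(x_j))^2 / m} / (\max_j f(x_j) - \min_j f(x_j))}
#'
#' Dividing by the predicted range makes the statistic comparable across
#' genes with different absolute expression levels; it is invariant to a
#' common affine transform of `y` and `f`.
#'
#' When the predicted range is degenerate — a flat curve, or any fit whose
#' predictions are nearly constant relative to the data (predicted range below
#' `tol` times the observed range) — the observed range of `y` is substituted
#' as the denominator and the result carries the attribute
#' `range_fallback = TRUE`. Without this substitution a nearly constant fit
#' gets an arbitrarily inflated RPE driven by its own vanishing range, which
#' destabilizes both the model-cascade guard and the selection among poor
#' fits. If both ranges are degenerate the RPE is 0 for a perfect fit and
#' `Inf` otherwise.
#'
#' @param y Observed responses at the evaluation points.
#' @param f Predicted responses at the same points (same length, >= 2).
#' @param tol Relative tolerance below which the predicted range counts as
#'   degenerate (fraction of the observed range). Default 0.1.
#' @return RPE in percent (numeric scalar), possibly with attribute
#'   `range_fallback`.
#' @examples
#' rpe(c(1, 2, 3, 4, 5, 6, 7), c(2, 2, 3, 4, 5, 6, 6))  # ~13.363
#' @export
rpe <- function(y, f, tol = 0.1) {
  if (length(y) != length(f)) stop("y and f must have equal length")
  if (length(y) < 2) stop("need at least 2 evaluation points")
  if (any(!is.finite(y)) || any(!is.finite(f))) return(Inf)
  rmse <- sqrt(mean((y - f)^2))
  rng_f <- max(f) - min(f)
  rng_y <- max(y) - min(y)
  if (rng_f >= tol * max(rng_y, .Machine$double.eps)) {
    return(100 * rmse / rng_f)
  }
  # degenerate predicted range (flat curve): fall back to observed range
  if (rng_y > 0) {
    return(structure(100 * rmse / rng_y, range_fallback = TRUE))
  }
  structure(if (rmse == 0) 0 else Inf, range_fallback = TRUE)
}

#' AIC on the evaluation points
#'
#' A diagnostic companion to the RPE: an AIC-style score computed on the
#' held-out evaluation points rather than the fitted points,
#' `m * log(SSE / m) + 2 * k` (natural log), where `m` is the number of
#' evaluation points and `k` the number of model parameters. A perfect fit
#' (SSE = 0) returns `-Inf` as a sentinel.
#'
#' @param y Observed responses at the evaluation points.
#' @param f Predicted responses at the same points.
#' @param k Number of model parameters (>= 1).
#' @return Numeric scalar.
#' @examples
#' aic_eval(c(1, 2, 3, 4, 5, 6, 7), c(2, 2, 3, 4, 5, 6, 6), k = 2)
#' @export
aic_eval <- function(y, f, k) {
  if (length(y) != length(f)) stop("y and f must have equal length")
  m <- length(y)
  if (m < 2) stop("need at least 2 evaluation points")
  if (k < 1) stop("k must be >= 1")
  sse <- sum((y - f)^2)
  if (sse == 0) return(-Inf)
  m * log(sse / m) + 2 * k
}
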