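# Linear volume -> body-weight model and its error diagnostics.

#' Fit the volume-to-body-weight line
#'
#' Closed-form simple least squares: slope
#' `a = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)`, intercept
#' `b = ybar - a * xbar`, goodness of fit
#' `R^2 = 1 - sum((y - f)^2) / sum((y - ybar)^2)`, and the Pearson
#' product-moment correlation `r`. For a simple linear fit `R^2 = r^2`
#' identically.
#'
#' @param volumes numeric vector of body volumes ((input unit)^3).
#' @param weights numeric vector of body weights (kg), same length.
#' @return an object of class `weight_model` with fields `a` (kg per volume
#'   unit), `b` (kg), `r`, `r_squared`, `n`.
#' @export
fit_weight_model <- function(volumes, weights) {
  x <- as.numeric(volumes)
  y <- as.numeric(weights)
  if (length(x) != length(y)) stop("volumes and weights must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("zero variance in volumes: slope undefined")
  a <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b <- mean(y) - a * mean(x)
  f <- a * x + b
  syy <- sum((y - mean(y))^2)
  r_squared <- if (syy > 0) 1 - sum((y - f)^2) / syy else 1
  r <- if (syy > 0) {
    sum((x - mean(x)) * (y - mean(y))) / sqrt(sxx * syy)
  } else 0
  structure(list(a = a, b = b, r = r, r_squared = r_squared,
                 n = length(x)),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("<weight_model> y = %.6g x + %.6g  (r = %.4f, R^2 = %.4f, n = %d)\n",
              x$a, x$b, x$r, x$r_squared, x$n))
  invisible(x)
}

#' Predict body weight from volume
#'
#' @param model a [fit_weight_model()] result (or any list with `a`, `b`).
#' @param volume body volume(s).
#' @return predicted weight(s) in kg: `a * volume + b`.
#' @export
predict_weight <- function(model, volume) {
  model$a * volume + model$b
}

#' Absolute and relative error statistics of weight predictions
#'
#' Absolute error is `|predicted - actual|` (kg); relative error is
#' `100 * |predicted - actual| / actual` (percent, denominator = actual
#' weight). Quartiles use linear interpolation between order statistics
#' (the common "type 7" convention).
#'
#' @param predicted predicted weights (kg).
#' @param actual actual weights (kg), strictly positive.
#' @return an object of class `error_stats` with `max_abs`, `min_abs`,
#'   `mean_abs`, `q1_abs`, `q3_abs` (kg) and `max_rel`, `min_rel`,
#'   `mean_rel`, `q1_rel`, `q3_rel` (percent).
#' @export
evaluate_errors <- function(predicted, actual) {
  p <- as.numeric(predicted)
  a <- as.numeric(actual)
  if (length(p) != length(a)) stop("predicted and actual must have equal length")
  if (length(p) < 1L) stop("need at least one pair")
  if (any(a <= 0)) stop("actual weights must be positive")
  abs_err <- abs(p - a)
  rel_err <- 100 * abs_err / a
  q <- function(v, probs) unname(quantile(v, probs, type = 7))
  structure(list(max_abs = max(abs_err), min_abs = min(abs_err),
                 mean_abs = mean(abs_err),
                 q1_abs = q(abs_err, 0.25), q3_abs = q(abs_err, 0.75),
                 max_rel = max(rel_err), min_rel = min(rel_err),
                 mean_rel = mean(rel_err),
                 q1_rel = q(rel_err, 0.25), q3_rel = q(rel_err, 0.75)),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats> abs [kg]: mean %.3f (min %.3f, Q1 %.3f, Q3 %.3f, max %.3f)\n",
              x$mean_abs, x$min_abs, x$q1_abs, x$q3_abs, x$max_abs))
  cat(sprintf("              rel [%%]: mean %.3f (min %.3f, Q1 %.3f, Q3 %.3f, max %.3f)\n",
              x$mean_rel, x$min_rel, x$q1_rel, x$q3_rel, x$max_rel))
  invisible(x)
}
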