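#' @importFrom rlang .data
#' @importFrom stats rnorm sd
NULL

#' Sample skewness
#' @param x Numeric vector.
#' @return The g1 moment-based skewness estimate.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# Normality gate shared by preprocessing and the change-summary tests:
# a feature is treated as non-normal when the Shapiro-Wilk test rejects at
# `alpha` AND the absolute skewness exceeds `skew_gate` (the skew condition
# guards against the test's oversensitivity at large n).
normality_gate_fails <- function(x, alpha = 0.05, skew_gate = 1) {
  x <- x[!is.na(x)]
  if (length(x) < 4 || stats::sd(x) == 0) return(FALSE)
  if (length(x) > 4500) {                 # shapiro.test caps at n = 5000
    x <- x[round(seq(1, length(x), length.out = 4500))]
  }
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 1)
  p < alpha && abs(sample_skewness(x)) > skew_gate
}

#' Softmax over the rows of a matrix (or a vector)
#' @param x Numeric matrix (rows are distributions) or vector.
#' @return Matrix/vector of the same shape, rows summing to one.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) {
    e <- exp(x - max(x))
    return(e / sum(e))
  }
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

rmse <- function(pred, truth) sqrt(mean((pred - truth)^2, na.rm = TRUE))

r_squared <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  1 - sum((truth[ok] - pred[ok])^2) / sum((truth[ok] - mean(truth[ok]))^2)
}

# Mean absolute percentage error, excluding near-zero truths where the
# ratio blows up.
mape <- function(pred, truth, min_abs = 0.1) {
  ok <- !is.na(pred) & !is.na(truth) & abs(truth) >= min_abs
  if (!any(ok)) return(NA_real_)
  100 * mean(abs((pred[ok] - truth[ok]) / truth[ok]))
}
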