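# Small numeric helpers shared across modules.

#' Softplus and its inverse
#'
#' `softplus(x) = log(1 + exp(x))`, the smooth rectifier used as the rate
#' link of the synthetic spike generator. `softplus_inv(y)` returns the
#' argument whose softplus equals `y`, useful to set a baseline parameter so
#' that the rectified baseline rate is exactly a target value in Hz.
#'
#' @param x,y numeric vectors.
#' @return numeric vector.
#' @examples
#' softplus(softplus_inv(5))  # 5
#' @export
softplus <- function(x) {
  # numerically stable: log1p(exp(-|x|)) + max(x, 0)
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' @rdname softplus
#' @export
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  y + log(-expm1(-y))
}

# Population (n-denominator) standard deviation.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# z-score with population SD; error on zero variance is handled by callers.
zscore_pop <- function(x) {
  s <- sd_pop(x)
  (x - mean(x)) / s
}

#' Empirical two-sided permutation p-value
#'
#' `(1 + #{|s_i - m| >= |obs - m|}) / (n + 1)` where `m` is the surrogate
#' mean. The +1 correction keeps the p-value achievable and strictly
#' positive.
#'
#' @param observed scalar statistic.
#' @param surrogates numeric vector of surrogate statistics.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(observed, surrogates) {
  m <- mean(surrogates)
  (1 + sum(abs(surrogates - m) >= abs(observed - m))) / (length(surrogates) + 1)
}

# Draw integer circular shifts: |shift| uniform on [frac[1]*L, frac[2]*L]
# strides, sign uniform. Uses the session RNG stream.
draw_shifts <- function(n, L, frac = c(0.2, 0.5)) {
  lo <- ceiling(frac[1] * L)
  hi <- floor(frac[2] * L)
  if (hi < lo) stop("series too short for the requested circular shifts")
  s <- lo + floor(runif(n) * (hi - lo + 1))
  s <- pmin(s, hi)
  sgn <- ifelse(runif(n) < 0.5, -1L, 1L)
  as.integer(sgn * s)
}

# Rotate a vector circularly by k (positive k moves values forward).
rotate_vec <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# Standard error of the mean.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
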