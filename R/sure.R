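# Stein's unbiased risk estimate for soft thresholding, used to select
# per-level shrinkage thresholds in the wavelet domain.

#' Robust noise-scale estimate from finest-level wavelet coefficients
#'
#' Median absolute deviation around the median, rescaled by 1/0.6745 so
#' the estimate is consistent for Gaussian noise. Returns 0 when all
#' coefficients are equal (caller then skips thresholding).
#'
#' @param coeffs numeric vector of coefficient magnitudes (length >= 2).
#' @return noise scale, >= 0.
#' @export
estimate_noise_sigma <- function(coeffs) {
  if (length(coeffs) < 2L)
    stop("need at least 2 coefficients to estimate noise", call. = FALSE)
  median(abs(coeffs - median(coeffs))) / 0.6745
}

#' SURE risk of a soft-threshold estimator
#'
#' For data `x_i ~ N(mu_i, sigma^2)` and the soft-threshold estimator
#' with threshold `t`, the unbiased risk estimate has the closed form
#' `d*sigma^2 + sum_i min(x_i^2, t^2) - 2*sigma^2 * #\{|x_i| <= t\}`.
#'
#' @param t candidate threshold, >= 0.
#' @param x numeric vector of coefficients (one level).
#' @param sigma noise scale, > 0.
#' @return estimated risk.
#' @export
sure_risk <- function(t, x, sigma) {
  if (length(t) != 1L || is.na(t) || t < 0)
    stop("threshold t must be a single non-negative number", call. = FALSE)
  stopifnot(length(x) >= 1L, sigma > 0)
  d <- length(x)
  d * sigma^2 + sum(pmin(x^2, t^2)) - 2 * sigma^2 * sum(abs(x) <= t)
}

#' Select the SURE-optimal soft threshold
#'
#' The SURE curve is piecewise smooth with minima attained on the set
#' of coefficient magnitudes (or at 0), so the search is exact over
#' `\{0\} U \{|x_i|\}`; ties break toward the smaller threshold.
#'
#' @inheritParams sure_risk
#' @return the minimizing threshold.
#' @export
select_sure_threshold <- function(x, sigma) {
  stopifnot(length(x) >= 1L, sigma > 0)
  cand <- sort(unique(c(0, abs(x))))
  risks <- vapply(cand, sure_risk, numeric(1), x = x, sigma = sigma)
  cand[which.min(risks)]  # which.min takes the first = smallest t on ties
}
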