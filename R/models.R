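#' Peak parameter vector for the mAPV model
#'
#' The modified asymmetric pseudo-Voigt (mAPV) profile describes one
#' peak with six parameters: height `H`, summit location `alpha` (u),
#' half-width-at-half-maximum of the left (`sigma1`) and right
#' (`sigma2`) halves, and the Lorentzian fractions `beta1`, `beta2` of
#' the two halves (the Gaussian fractions are `1 - beta`).
#'
#' @param H peak height, > 0.
#' @param alpha summit m/z (u).
#' @param sigma1,sigma2 half-widths at half maximum of the two halves, > 0.
#' @param beta1,beta2 Lorentz fractions in `[0, 1]`.
#' @return A named numeric vector of class `peak_params`.
#' @export
#' @examples
#' th <- peak_params(100, 500, 2, 4, 0.3, 0.7)
#' mapv_eval(500, th)   # equals H
peak_params <- function(H, alpha, sigma1, sigma2, beta1, beta2) {
  th <- c(H = as.numeric(H), alpha = as.numeric(alpha),
          sigma1 = as.numeric(sigma1), sigma2 = as.numeric(sigma2),
          beta1 = as.numeric(beta1), beta2 = as.numeric(beta2))
  validate_peak_params(th)
  structure(th, class = "peak_params")
}

validate_peak_params <- function(th) {
  if (anyNA(th) || length(th) != 6L)
    stop("peak parameters must be 6 finite numbers", call. = FALSE)
  if (th[["H"]] <= 0) stop("H must be > 0", call. = FALSE)
  if (th[["sigma1"]] <= 0 || th[["sigma2"]] <= 0)
    stop("sigma1 and sigma2 must be > 0", call. = FALSE)
  if (th[["beta1"]] < 0 || th[["beta1"]] > 1 ||
      th[["beta2"]] < 0 || th[["beta2"]] > 1)
    stop("beta1 and beta2 must lie in [0, 1]", call. = FALSE)
  invisible(th)
}

as_theta <- function(theta) {
  # accept peak_params, named vector, or plain numeric of length 6 in
  # canonical order (H, alpha, sigma1, sigma2, beta1, beta2)
  if (inherits(theta, "peak_params")) return(unclass(theta))
  theta <- unlist(theta)
  if (is.null(names(theta)) || !all(c("H", "alpha") %in% names(theta)))
    names(theta) <- c("H", "alpha", "sigma1", "sigma2", "beta1", "beta2")
  validate_peak_params(theta)
  theta
}

#' Evaluate the mAPV peak profile
#'
#' For `m < alpha` the profile is a `beta1`-weighted sum of a Lorentzian
#' and a Gaussian, both with half-width `sigma1`; for `m >= alpha` the
#' same with `sigma2`, `beta2`. The profile is continuous at the summit
#' with value `H`, and equals `H/2` at `alpha - sigma1` and
#' `alpha + sigma2` for every beta.
#'
#' @param m numeric vector of m/z values.
#' @param theta a [peak_params()] (or named/ordered numeric of length 6).
#' @return intensities, same length as `m`.
#' @export
mapv_eval <- function(m, theta) {
  th <- as_theta(theta)
  left <- m < th[["alpha"]]
  sig <- ifelse(left, th[["sigma1"]], th[["sigma2"]])
  bet <- ifelse(left, th[["beta1"]], th[["beta2"]])
  z2 <- ((m - th[["alpha"]]) / sig)^2
  th[["H"]] * (bet / (1 + z2) + (1 - bet) * exp(-log(2) * z2))
}

# Batch SSE objective factory: returns a function mapping an n x d
# matrix of parameter rows (canonical order) to an n-vector of sums of
# squared residuals against (m, y). Hot path of the swarm fit, backed
# by the compiled kernel.
make_sse_objective <- function(m, y, model = c("mapv", "gaussian",
                                               "lorentz", "bigaussian")) {
  model <- match.arg(model)
  code <- match(model, c("mapv", "gaussian", "lorentz", "bigaussian")) - 1L
  force(m); force(y)
  function(Theta) {
    if (!is.matrix(Theta)) Theta <- matrix(Theta, nrow = 1L)
    sse_batch_cpp(Theta, m, y, code)
  }
}

# single-shot convenience used in tests and examples
mapv_sse_batch <- function(Theta, m, y, model = "mapv") {
  make_sse_objective(m, y, model)(Theta)
}

#' Comparison peak profiles: Gaussian, Lorentz, Bi-Gaussian
#'
#' All use the same half-width-at-half-maximum parameterization as the
#' mAPV model, to which they degenerate: `mapv_eval` with
#' `beta1 = beta2 = 0, sigma1 = sigma2` is Gaussian, with
#' `beta1 = beta2 = 1` Lorentzian, and with `beta1 = beta2 = 0` (free
#' sigmas) Bi-Gaussian.
#'
#' @param m numeric vector of m/z values.
#' @param H peak height, > 0.
#' @param alpha summit m/z.
#' @param sigma,sigma1,sigma2 half-widths at half maximum, > 0.
#' @return intensities, same length as `m`.
#' @export
gaussian_eval <- function(m, H, alpha, sigma) {
  stopifnot(H > 0, sigma > 0)
  H * exp(-log(2) * ((m - alpha) / sigma)^2)
}

#' @rdname gaussian_eval
#' @export
lorentz_eval <- function(m, H, alpha, sigma) {
  stopifnot(H > 0, sigma > 0)
  H / (1 + ((m - alpha) / sigma)^2)
}

#' @rdname gaussian_eval
#' @export
bigaussian_eval <- function(m, H, alpha, sigma1, sigma2) {
  stopifnot(H > 0, sigma1 > 0, sigma2 > 0)
  sig <- ifelse(m < alpha, sigma1, sigma2)
  H * exp(-log(2) * ((m - alpha) / sig)^2)
}

#' Analytic area under an mAPV peak
#'
#' Integral of [mapv_eval()] over the whole real line. Each half
#' contributes `H * sigma * (beta * pi/2 + (1 - beta) * sqrt(pi/log 2)/2)`
#' (half-Lorentzian plus half-Gaussian areas in the HWHM
#' parameterization).
#'
#' @inheritParams mapv_eval
#' @return area (intensity x u).
#' @export
peak_area <- function(theta) {
  th <- as_theta(theta)
  half <- function(sigma, beta)
    sigma * (beta * pi / 2 + (1 - beta) * 0.5 * sqrt(pi / log(2)))
  th[["H"]] * (half(th[["sigma1"]], th[["beta1"]]) +
               half(th[["sigma2"]], th[["beta2"]]))
}

# Analytic area of the comparison models (same HWHM parameterization).
model_area <- function(model, par) {
  switch(model,
    gaussian = par[[1]] * par[[3]] * sqrt(pi / log(2)),
    lorentz = par[[1]] * par[[3]] * pi,
    bigaussian = par[[1]] * (par[[3]] + par[[4]]) / 2 * sqrt(pi / log(2)),
    mapv = peak_area(par),
    stop("unknown model: ", model, call. = FALSE))
}

#' Peak asymmetry ratio
#'
#' `mu = max(sigma1, sigma2) / min(sigma1, sigma2) >= 1`. Values above 2
#' flag a highly asymmetric fit that may hide overlapping peaks.
#'
#' @inheritParams mapv_eval
#' @return asymmetry ratio >= 1.
#' @export
asymmetry <- function(theta) {
  th <- as_theta(theta)
  max(th[["sigma1"]], th[["sigma2"]]) / min(th[["sigma1"]], th[["sigma2"]])
}
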