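# Peak picking: valley segmentation, per-component mAPV fitting by
# HPSO, and recursive decomposition of broad / highly asymmetric
# components at their interior valleys.

#' Detector configuration
#'
#' @param area_threshold minimum fitted peak area to keep; `NULL` means
#'   the data-driven default `5 * noise_sigma * median(diff(mz))`, with
#'   the noise scale taken from the median absolute first difference of
#'   the corrected spectrum.
#' @param width_threshold maximum credible single-peak width (FWHM =
#'   `sigma1 + sigma2`, in u); wider fits are re-split at interior
#'   valleys. The default `Inf` disables the width rule: peak width is a
#'   physical property of the instrument that no grid-derived default
#'   can guess, and the asymmetry rule already drives the overlap
#'   decomposition. Supply an instrument-informed value to enable it.
#' @param asymmetry_threshold asymmetry ratio above which a fit is
#'   treated as possibly containing overlapping peaks (default 2).
#' @param max_depth recursion cap for component splitting.
#' @param min_points minimum data points per fittable component.
#' @param valley_tolerance intensity tolerance below which neighbouring
#'   valleys are merged in the initial segmentation (the barrier between
#'   them is treated as noise); `NULL` means `3 * noise_sigma` of the
#'   corrected spectrum. The recursive re-split of suspicious components
#'   always uses tolerance 0, so dips hidden by the initial merge can
#'   still be recovered when a fit is too wide or too asymmetric.
#' @return a `detector_config` list.
#' @export
detector_config <- function(area_threshold = NULL, width_threshold = Inf,
                            asymmetry_threshold = 2, max_depth = 3L,
                            min_points = 5L, valley_tolerance = NULL) {
  stopifnot(asymmetry_threshold > 1, max_depth >= 1L, min_points >= 3L,
            is.null(valley_tolerance) || valley_tolerance >= 0)
  structure(list(area_threshold = area_threshold,
                 width_threshold = width_threshold,
                 asymmetry_threshold = asymmetry_threshold,
                 max_depth = as.integer(max_depth),
                 min_points = as.integer(min_points),
                 valley_tolerance = valley_tolerance),
            class = "detector_config")
}

#' Locate valleys (interior local minima) in an intensity vector
#'
#' A valley is an interior index whose value is <= both neighbours;
#' plateaus of equal values count once, at their midpoint index. When
#' `tolerance > 0`, valleys are pruned by prominence: the valley whose
#' shallower exit barrier (the climb to the highest point separating it
#' from the adjacent surviving valley or the range end) is smallest is
#' removed while that climb is below `tolerance`, merging noise dips
#' into their neighbouring basins while deep valleys survive.
#'
#' @param intensity numeric vector.
#' @param tolerance intensity tolerance below which a valley's exit
#'   barrier marks it as noise.
#' @return sorted integer vector of valley indices (possibly empty).
#' @export
find_valleys <- function(intensity, tolerance = 0) {
  n <- length(intensity)
  if (n < 3L) return(integer(0))
  r <- rle(intensity)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- integer(0)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      if (r$values[j] <= r$values[j - 1L] && r$values[j] <= r$values[j + 1L])
        vals <- c(vals, (starts[j] + ends[j]) %/% 2L)
    }
  }
  if (tolerance > 0) {
    while (length(vals) > 0L) {
      bounds <- c(1L, vals, n)
      prom <- vapply(seq_along(vals), function(i) {
        v <- vals[i]
        min(max(intensity[bounds[i]:v]),
            max(intensity[v:bounds[i + 2L]])) - intensity[v]
      }, numeric(1))
      if (min(prom) >= tolerance) break
      vals <- vals[-which.min(prom)]
    }
  }
  vals
}

#' Split an index range into components at its valleys
#'
#' Each valley index is shared by both adjacent components (closed on
#' both ends) so fitted peaks meet at the valleys; with `v` valleys the
#' spectrum yields `v + 1` components.
#'
#' @param intensity numeric vector.
#' @param tolerance passed to [find_valleys()].
#' @return list of integer index ranges (`start:end` vectors).
#' @export
split_at_valleys <- function(intensity, tolerance = 0) {
  n <- length(intensity)
  vals <- find_valleys(intensity, tolerance)
  cuts <- c(1L, vals, n)
  lapply(seq_len(length(cuts) - 1L),
         function(i) cuts[i]:cuts[i + 1L])
}

# data-driven HPSO search box for one component's points
fit_bounds <- function(m, y, model) {
  dm <- median(diff(m))
  span <- m[length(m)] - m[1L]
  ymax <- max(y)
  lower <- c(H = 0.5 * ymax, alpha = m[1L], sigma1 = dm)
  upper <- c(H = 2 * ymax, alpha = m[length(m)], sigma1 = span)
  if (model %in% c("bigaussian", "mapv")) {
    lower <- c(lower, sigma2 = dm)
    upper <- c(upper, sigma2 = span)
  }
  if (model == "mapv") {
    lower <- c(lower, beta1 = 0, beta2 = 0)
    upper <- c(upper, beta1 = 1, beta2 = 1)
  }
  rbind(lower, upper)
}

# Fit one peak model to (m, y) points by HPSO. `hpso` carries every
# swarm setting except the bounds, which are data-driven.
fit_peak_model <- function(m, y, model = "mapv", hpso = list()) {
  bounds <- fit_bounds(m, y, model)
  args <- modifyList(list(bounds = bounds), hpso)
  cfg <- do.call(hpso_config, args)
  hpso_optimize(make_sse_objective(m, y, model), cfg)
}

#' Fit an mAPV peak to one component
#'
#' Minimizes the sum of squared residuals over the six mAPV parameters
#' with HPSO inside a data-driven box: `H` within a factor 2 of the
#' component maximum, `alpha` inside the component's m/z window, the
#' sigmas between the grid spacing and the window span, and the betas
#' in `[0, 1]`.
#'
#' @param m,intensity the component's points (>= `min_points`, positive
#'   maximum).
#' @param hpso list of [hpso_config()] overrides (e.g. `seed`,
#'   `max_iter`).
#' @param min_points minimum number of points required.
#' @return a `fitted_peak`: list with `theta` ([peak_params()]), `area`,
#'   `mu`, `sse`, `start_mz`, `end_mz`.
#' @export
fit_component <- function(m, intensity, hpso = list(), min_points = 5L) {
  if (length(m) < min_points)
    stop("insufficient points to fit a component (need >= ", min_points,
         ")", call. = FALSE)
  if (max(intensity) <= 0)
    stop("empty component: no positive intensity", call. = FALSE)
  fit <- fit_peak_model(m, intensity, "mapv", hpso)
  theta <- do.call(peak_params, as.list(fit$theta))
  structure(list(theta = theta, area = peak_area(theta),
                 mu = asymmetry(theta), sse = fit$value,
                 start_mz = m[1L], end_mz = m[length(m)]),
            class = "fitted_peak")
}

fitted_peak_row <- function(fp) {
  th <- fp$theta
  data.frame(summit_mz = th[["alpha"]], height = th[["H"]],
             sigma1 = th[["sigma1"]], sigma2 = th[["sigma2"]],
             beta1 = th[["beta1"]], beta2 = th[["beta2"]],
             area = fp$area, asymmetry = fp$mu,
             start_mz = fp$start_mz, end_mz = fp$end_mz, sse = fp$sse)
}

# robust noise scale of a (corrected) spectrum from first differences
spectrum_noise_sigma <- function(s) {
  median(abs(diff(s$intensity))) / (0.6745 * sqrt(2))
}

# Default data-driven area threshold: five noise sigmas sustained over a
# minimal credible peak width of ten sample spacings. The noise scale is
# the MAD of the corrected intensities, which (unlike a first-difference
# estimator) still sees the correlated ripple that wavelet smoothing
# leaves behind -- the stuff that produces spurious components.
default_area_threshold <- function(s) {
  sigma <- median(abs(s$intensity - median(s$intensity))) / 0.6745
  5 * sigma * 10 * median(diff(s$mz))
}

#' Detect peaks in a preprocessed spectrum
#'
#' Implements the valley-segmentation / model-fitting recursion: split
#' the spectrum at its valleys; fit an mAPV peak to each component;
#' drop fits with area below `area_threshold`; re-split a component at
#' its interior valleys and recurse (up to `max_depth`) when the fitted
#' width (`sigma1 + sigma2`) exceeds `width_threshold` or the fit is
#' highly asymmetric (`mu > asymmetry_threshold`) -- in either case only
#' if interior valleys exist, otherwise the single fit is kept.
#' Components whose fitted summit escapes their m/z window are dropped
#' with a warning.
#'
#' @param s a smoothed, baseline-corrected [mass_spectrum()] (a warning
#'   is issued, and detection proceeds, if the preprocessing stages are
#'   not recorded in the metadata).
#' @param cfg a [detector_config()].
#' @param hpso list of [hpso_config()] overrides for the per-component
#'   fits (e.g. `seed`, `max_iter`, `n_particles`).
#' @return a [peak_table()] sorted by summit m/z.
#' @export
detect_peaks <- function(s, cfg = detector_config(), hpso = list()) {
  stopifnot(is_spectrum(s))
  if (!"baseline_corrected" %in% spectrum_stage(s))
    warning("spectrum does not appear to be preprocessed; ",
            "detecting peaks anyway", call. = FALSE)
  area_thr <- if (is.null(cfg$area_threshold)) default_area_threshold(s)
              else cfg$area_threshold
  width_thr <- if (is.null(cfg$width_threshold)) Inf
               else cfg$width_threshold
  valley_tol <- if (is.null(cfg$valley_tolerance))
                  3 * spectrum_noise_sigma(s)
                else cfg$valley_tolerance
  if (max(s$intensity) <= 0) return(peak_table())

  n_total <- length(s$intensity)
  peaks <- list()
  process <- function(idx, depth) {
    m <- s$mz[idx]
    y <- s$intensity[idx]
    if (length(idx) < cfg$min_points || max(y) <= 0) return(invisible())
    # a peak candidate must carry its own summit: a component whose
    # maximum sits on a cut boundary (not a spectrum end) is a monotone
    # flank fragment, not a peak
    i_max <- which.max(y)
    if ((i_max == 1L && idx[1L] != 1L) ||
        (i_max == length(y) && idx[length(idx)] != n_total))
      return(invisible())
    # cheap bound: the trapezoidal data area caps what a fit retained by
    # the area filter could reach; skip the expensive fit for clear noise
    if (sum(diff(m) * (head2(y) + tail2(y)) / 2) < 0.5 * area_thr)
      return(invisible())
    fp <- fit_component(m, y, hpso, cfg$min_points)
    if (fp$area < area_thr) return(invisible())
    wide <- (fp$theta[["sigma1"]] + fp$theta[["sigma2"]]) > width_thr
    asym <- fp$mu > cfg$asymmetry_threshold
    if ((wide || asym) && depth < cfg$max_depth) {
      # the re-split ignores the merge tolerance: any interior dip that
      # the initial segmentation smoothed over is now fair game
      inner <- find_valleys(y, 0)
      if (length(inner) > 0L) {
        for (sub in split_at_valleys(y, 0))
          process(idx[sub], depth + 1L)
        return(invisible())
      }
    }
    alpha <- fp$theta[["alpha"]]
    if (alpha < m[1L] || alpha > m[length(m)]) {
      warning("fitted summit outside its component; dropping", call. = FALSE)
      return(invisible())
    }
    peaks[[length(peaks) + 1L]] <<- fp
    invisible()
  }
  for (idx in split_at_valleys(s$intensity, valley_tol))
    process(idx, 1L)
  if (length(peaks) == 0L) return(peak_table())
  tab <- do.call(rbind, lapply(peaks, fitted_peak_row))
  peak_table(tab[order(tab$summit_mz), ])
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1L]
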