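#' Wavelet shrinkage configuration
#'
#' Controls the dual-tree complex wavelet smoothing step. The spectrum
#' is split into `n_segments` equal-length contiguous sections that are
#' smoothed independently, because noise (and hence the right threshold)
#' decreases along a MALDI spectrum. `n_levels = NULL` picks
#' `floor(log2(segment length)) - 3`, clamped to `[3, 8]`, leaving the
#' coarse approximation untouched.
#'
#' @param n_segments number of independently smoothed sections (>= 1).
#' @param n_levels decomposition depth, or `NULL` for automatic.
#' @param qshift_filter identifier of the q-shift filter pair.
#' @param first_level_filter identifier of the level-1 biorthogonal pair.
#' @return a `wavelet_config` list.
#' @export
wavelet_config <- function(n_segments = 4L, n_levels = NULL,
                           qshift_filter = "qshift_14",
                           first_level_filter = "near_sym_5_7") {
  stopifnot(n_segments >= 1L, is.null(n_levels) || n_levels >= 1L)
  structure(list(n_segments = as.integer(n_segments),
                 n_levels = if (!is.null(n_levels)) as.integer(n_levels),
                 qshift_filter = qshift_filter,
                 first_level_filter = first_level_filter),
            class = "wavelet_config")
}

auto_levels <- function(n) {
  max(3L, min(8L, as.integer(floor(log2(n))) - 3L))
}

# SURE soft shrinkage of the complex detail magnitudes of one segment;
# phase (the dA/dB ratio) is preserved.
shrink_segment <- function(x, cfg, filters) {
  n <- length(x)
  n_levels <- if (is.null(cfg$n_levels)) auto_levels(n) else cfg$n_levels
  n_levels <- min(n_levels, max(1L, as.integer(floor(log2(n))) - 1L))
  w <- dtcwt_forward(x, n_levels, filters)
  mag1 <- sqrt(w$detail_a[[1L]]^2 + w$detail_b[[1L]]^2)
  sigma <- estimate_noise_sigma(mag1)
  if (sigma <= 0) return(x)  # no dispersion at the finest level
  for (j in seq_len(n_levels)) {
    mag <- sqrt(w$detail_a[[j]]^2 + w$detail_b[[j]]^2)
    t_j <- select_sure_threshold(mag, sigma)
    scale <- ifelse(mag > 0, pmax(mag - t_j, 0) / mag, 0)
    w$detail_a[[j]] <- w$detail_a[[j]] * scale
    w$detail_b[[j]] <- w$detail_b[[j]] * scale
  }
  dtcwt_inverse(w, filters)
}

#' Smooth a spectrum by dual-tree complex wavelet shrinkage
#'
#' The intensity vector is split into `cfg$n_segments` equal-length
#' contiguous sections (the last absorbs any remainder). Each section is
#' transformed with the dual-tree complex wavelet transform, its complex
#' detail magnitudes are soft-thresholded at a per-level SURE-selected
#' threshold (phase preserved, noise scale from the finest level), and
#' inverse-transformed. The m/z axis and the length are unchanged.
#'
#' @param s a [mass_spectrum()].
#' @param cfg a [wavelet_config()].
#' @return the smoothed [mass_spectrum()] (stage `"smoothed"` recorded;
#'   intensities may now be slightly negative).
#' @export
smooth_spectrum <- function(s, cfg = wavelet_config()) {
  stopifnot(is_spectrum(s))
  n <- length(s$mz)
  if (n < 2L * cfg$n_segments)
    stop("spectrum too short for ", cfg$n_segments, " segments",
         call. = FALSE)
  filters <- dtcwt_filters(cfg$qshift_filter, cfg$first_level_filter)
  seg_len <- n %/% cfg$n_segments
  out <- numeric(n)
  for (k in seq_len(cfg$n_segments)) {
    lo <- (k - 1L) * seg_len + 1L
    hi <- if (k == cfg$n_segments) n else k * seg_len
    out[lo:hi] <- shrink_segment(s$intensity[lo:hi], cfg, filters)
  }
  res <- mass_spectrum(s$mz, out, s$metadata, allow_negative = TRUE)
  add_stage(res, "smoothed")
}

#' Monotone local-minimum baseline estimate
#'
#' The baseline follows the spectrum while it decreases and stays flat
#' while it increases: `b[1] = y[1]`, `b[i] = min(b[i-1], y[i])` (a
#' running minimum). Suited to MALDI baselines, which fall steeply at
#' low mass and then level off.
#'
#' @param s a [mass_spectrum()] (normally already smoothed).
#' @return numeric baseline vector, non-increasing.
#' @export
estimate_baseline <- function(s) {
  stopifnot(is_spectrum(s))
  cummin(s$intensity)
}

#' Subtract a baseline from a spectrum
#'
#' Residual negatives (possible only through numerical noise, since the
#' baseline is a running minimum) are clipped to zero.
#'
#' @param s a [mass_spectrum()].
#' @param baseline numeric vector from [estimate_baseline()].
#' @return baseline-corrected [mass_spectrum()] (stage recorded).
#' @export
correct_baseline <- function(s, baseline) {
  stopifnot(is_spectrum(s))
  if (length(baseline) != length(s$mz))
    stop("baseline length must match the spectrum", call. = FALSE)
  res <- mass_spectrum(s$mz, pmax(s$intensity - baseline, 0), s$metadata,
                       allow_negative = TRUE)
  add_stage(res, "baseline_corrected")
}

#' Full preprocessing: smoothing plus baseline correction
#'
#' @param s a raw [mass_spectrum()].
#' @param cfg a [wavelet_config()].
#' @param baseline apply baseline correction (default `TRUE`).
#' @return the preprocessed [mass_spectrum()].
#' @export
preprocess_spectrum <- function(s, cfg = wavelet_config(), baseline = TRUE) {
  s <- smooth_spectrum(s, cfg)
  if (baseline) s <- correct_baseline(s, estimate_baseline(s))
  s
}
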