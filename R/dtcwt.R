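# 1-D dual-tree complex wavelet transform.
#
# Two parallel critically sampled real wavelet trees whose detail
# coefficients form the real and imaginary parts of approximately
# analytic complex coefficients, giving near shift-invariance at 2x
# redundancy. Level 1 uses an odd-length biorthogonal near-symmetric
# (5,7)-tap pair with tree B offset by one sample; levels >= 2 use an
# orthonormal 14-tap q-shift filter whose time reverse (tree B) supplies
# the +/- quarter-sample delays of the Hilbert pair.
#
# All filtering is circular via FFT. Inputs are symmetrically extended
# to an even power-of-two-friendly length before the transform, so the
# circular wrap never crosses a discontinuity.

# Published 14-tap q-shift orthonormal lowpass (sum = sqrt(2); the
# double-shift orthonormality holds to the printed 1e-8 precision).
qshift_14 <- c(0.00325314, -0.00388321, 0.03466035, -0.03887280,
               -0.11720389, 0.27529538, 0.75614564, 0.56881042,
               0.01186609, -0.10671180, 0.02382538, 0.01702522,
               -0.00543948, -0.00455690)

# (5,7)-tap near-symmetric biorthogonal pair, sqrt(2)-normalized.
nearsym_h0 <- sqrt(2) * c(-1, 5, 12, 5, -1) / 20
nearsym_g0 <- sqrt(2) * c(-3, -15, 73, 170, 73, -15, -3) / 280

dtcwt_filters <- function(qshift_filter = "qshift_14",
                          first_level_filter = "near_sym_5_7") {
  if (!identical(qshift_filter, "qshift_14"))
    stop("unknown q-shift filter: ", qshift_filter, call. = FALSE)
  if (!identical(first_level_filter, "near_sym_5_7"))
    stop("unknown first-level filter: ", first_level_filter, call. = FALSE)
  altflip <- function(h) rev(h) * (-1)^(seq_along(h) - 1L)
  list(
    h0o = nearsym_h0, g0o = nearsym_g0,
    h1o = (-1)^(seq_along(nearsym_g0)) * nearsym_g0,   # analysis highpass
    g1o = -(-1)^(seq_along(nearsym_h0)) * nearsym_h0,  # synthesis highpass
    h0a = qshift_14,       h1a = altflip(qshift_14),
    h0b = rev(qshift_14),  h1b = altflip(rev(qshift_14)))
}

# circular convolution of x with filter h placed with tap `center`
# (1-based) at lag zero (zero phase for symmetric h)
circ_filter <- function(x, h, center) {
  n <- length(x)
  hp <- fold_filter(h, n, offset = 1L - center)
  Re(fft(fft(x) * fft(hp), inverse = TRUE)) / n
}

# fold a filter onto a circular buffer of length n (handles filters
# longer than the signal, which arise at the deepest levels)
fold_filter <- function(h, n, offset = 0L) {
  hp <- numeric(n)
  idx <- ((seq_along(h) - 1L + offset) %% n) + 1L
  for (i in seq_along(h)) hp[idx[i]] <- hp[idx[i]] + h[i]
  hp
}

# circular cross-correlation: C[l+1] = sum_n x[(n+l) mod N + 1] h[n+1]
circ_correlate <- function(x, h) {
  n <- length(x)
  hp <- fold_filter(h, n)
  Re(fft(fft(x) * Conj(fft(hp)), inverse = TRUE)) / n
}

# one orthonormal analysis / synthesis step (q-shift levels), with a
# downsampling phase (1 or 2) that also carries the level-1 tree offset
ana_step_orth <- function(x, h0, h1) {
  n <- length(x)
  list(a = circ_correlate(x, h0)[seq(1L, n, 2L)],
       d = circ_correlate(x, h1)[seq(1L, n, 2L)])
}

syn_step_orth <- function(a, d, h0, h1) {
  n <- 2L * length(a)
  ua <- numeric(n); ud <- numeric(n)
  ua[seq(1L, n, 2L)] <- a
  ud[seq(1L, n, 2L)] <- d
  hp0 <- fold_filter(h0, n)
  hp1 <- fold_filter(h1, n)
  Re(fft(fft(ua) * fft(hp0) + fft(ud) * fft(hp1), inverse = TRUE)) / n
}

# level-1 biorthogonal step; `phase` = 1 for tree A, 2 for tree B (the
# one-sample inter-tree offset). Lowpass is sampled on `phase`, highpass
# on the opposite parity (PR requirement of the odd/odd pair).
ana_step_bior <- function(x, f, phase) {
  n <- length(x)
  ya <- circ_filter(x, f$h0o, 3L)
  yd <- circ_filter(x, f$h1o, 4L)
  list(a = ya[seq(phase, n, 2L)],
       d = yd[seq(phase %% 2L + 1L, n, 2L)])
}

syn_step_bior <- function(a, d, f, phase) {
  n <- 2L * length(a)
  ua <- numeric(n); ud <- numeric(n)
  ua[seq(phase, n, 2L)] <- a
  ud[seq(phase %% 2L + 1L, n, 2L)] <- d
  circ_filter(ua, f$g0o, 4L) + circ_filter(ud, f$g1o, 3L)
}

# symmetric extension to length 2*M (M = next multiple of 2^levels),
# making the signal circularly continuous
dtcwt_extend <- function(x, n_levels) {
  n <- length(x)
  block <- 2L^n_levels
  m <- as.integer(ceiling(n / block) * block)
  if (m > n) {
    extra <- x[seq(n - 1L, by = -1L, length.out = m - n)]
    x <- c(x, extra)
  }
  c(x, rev(x))
}

#' Forward 1-D dual-tree complex wavelet transform
#'
#' @param x numeric signal (any length >= 4).
#' @param n_levels number of decomposition levels.
#' @param filters filter set from `dtcwt_filters()` (internal default).
#' @return list with per-level detail coefficient pairs
#'   `detail_a[[j]]`, `detail_b[[j]]`, final approximations `approx_a`,
#'   `approx_b`, and bookkeeping (`n`, `n_levels`).
#' @keywords internal
dtcwt_forward <- function(x, n_levels, filters = dtcwt_filters()) {
  stopifnot(n_levels >= 1L, length(x) >= 4L)
  n0 <- length(x)
  xe <- dtcwt_extend(x, n_levels)
  da <- vector("list", n_levels)
  db <- vector("list", n_levels)
  sa <- ana_step_bior(xe, filters, 1L)
  sb <- ana_step_bior(xe, filters, 2L)
  da[[1L]] <- sa$d; db[[1L]] <- sb$d
  aa <- sa$a; ab <- sb$a
  if (n_levels >= 2L) {
    for (j in 2:n_levels) {
      sa <- ana_step_orth(aa, filters$h0a, filters$h1a)
      sb <- ana_step_orth(ab, filters$h0b, filters$h1b)
      da[[j]] <- sa$d; db[[j]] <- sb$d
      aa <- sa$a; ab <- sb$a
    }
  }
  list(detail_a = da, detail_b = db, approx_a = aa, approx_b = ab,
       n = n0, n_levels = n_levels)
}

#' Inverse 1-D dual-tree complex wavelet transform
#'
#' Averages the two perfect-reconstruction tree inverses and trims the
#' symmetric extension.
#'
#' @param w transform object from [dtcwt_forward()].
#' @param filters filter set (must match the forward call).
#' @return numeric signal of the original length.
#' @keywords internal
dtcwt_inverse <- function(w, filters = dtcwt_filters()) {
  aa <- w$approx_a; ab <- w$approx_b
  if (w$n_levels >= 2L) {
    for (j in w$n_levels:2L) {
      aa <- syn_step_orth(aa, w$detail_a[[j]], filters$h0a, filters$h1a)
      ab <- syn_step_orth(ab, w$detail_b[[j]], filters$h0b, filters$h1b)
    }
  }
  xa <- syn_step_bior(aa, w$detail_a[[1L]], filters, 1L)
  xb <- syn_step_bior(ab, w$detail_b[[1L]], filters, 2L)
  ((xa + xb) / 2)[seq_len(w$n)]
}
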