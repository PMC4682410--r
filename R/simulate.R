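# Synthetic spectra with known truth: two-component mAPV mixtures for
# the model-comparison study, and multi-peak MALDI-like spectra with a
# decaying baseline and noise that shrinks along the m/z axis for
# end-to-end pipeline tests.

truth_table <- function(thetas, grid_range) {
  rows <- lapply(thetas, function(th) {
    th <- as_theta(th)
    data.frame(summit_mz = th[["alpha"]], height = th[["H"]],
               sigma1 = th[["sigma1"]], sigma2 = th[["sigma2"]],
               beta1 = th[["beta1"]], beta2 = th[["beta2"]],
               area = peak_area(th), asymmetry = asymmetry(th),
               start_mz = grid_range[1L], end_mz = grid_range[2L],
               sse = 0)
  })
  tab <- do.call(rbind, rows)
  peak_table(tab[order(tab$summit_mz), ])
}

#' Simulate a two-component mAPV spectrum
#'
#' Intensities are the sum of two mAPV profiles evaluated on a regular
#' grid plus i.i.d. Gaussian noise, clipped at zero; the returned truth
#' table carries the exact parameters and analytic areas.
#'
#' @param theta_a,theta_b [peak_params()] of the two components.
#' @param grid numeric `c(start, stop, spacing)` in u.
#' @param noise_sd additive noise standard deviation (intensity units).
#' @param seed RNG seed (`NULL` = leave the RNG state alone).
#' @return list with `spectrum` ([mass_spectrum()]) and `truth`
#'   ([peak_table()]).
#' @export
simulate_two_peak_spectrum <- function(theta_a, theta_b,
                                       grid = c(20, 120, 0.1),
                                       noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0, length(grid) == 3L, grid[2L] > grid[1L],
            grid[3L] > 0)
  if (!is.null(seed)) set.seed(seed)
  m <- seq(grid[1L], grid[2L], by = grid[3L])
  y <- mapv_eval(m, theta_a) + mapv_eval(m, theta_b)
  if (noise_sd > 0) y <- pmax(y + rnorm(length(m), 0, noise_sd), 0)
  list(spectrum = mass_spectrum(m, y, list(stage = "simulated")),
       truth = truth_table(list(theta_a, theta_b), range(m)))
}

#' Design grid for the two-peak model-comparison study
#'
#' Emulates the axes of the simulation study: five asymmetry levels
#' `mu in {1, 1.25, 1.5, 1.75, 2}` (both components constructed with
#' exactly that `sigma2/sigma1` ratio), a separation axis
#' `sep in {1, 2, 3, 4}` measured in units of the sum of the facing
#' half-widths `sigma2_a + sigma1_b` (so `sep = 1` means the summits are
#' just resolved, touching at half maximum, and `sep = 4` means baseline
#' separation), and noise at `{1, 2, 5}%` of the first
#' component height. Heights are drawn uniformly in `[50, 150]`, base
#' half-widths in `[1, 4]` u and Lorentz fractions from
#' `{0, 0.25, 0.5, 0.75, 1}`. The first summit sits at 50 u; the grid
#' spacing is 0.1 u with an 8-half-width margin on each side. Every
#' design is reproducible from `base_seed`, the setting index and the
#' replicate index alone.
#'
#' @param mu_levels asymmetry levels.
#' @param sep_levels separation multipliers.
#' @param noise_levels noise as a fraction of the component-a height.
#' @param reps replicates per setting.
#' @param base_seed integer seed from which every replicate seed is
#'   derived.
#' @return data frame of designs, one row per (setting, replicate),
#'   with list-columns `theta_a`, `theta_b` and columns `mu`, `sep`,
#'   `noise_frac`, `noise_sd`, `rep`, `seed`,
#'   `grid_start`, `grid_stop`, `grid_by`.
#' @export
dataset1_grid <- function(mu_levels = c(1, 1.25, 1.5, 1.75, 2),
                          sep_levels = 1:4,
                          noise_levels = c(0.01, 0.02, 0.05),
                          reps = 10L, base_seed = 1L) {
  stopifnot(length(mu_levels) >= 1L, length(sep_levels) >= 1L,
            length(noise_levels) >= 1L, reps >= 1L)
  settings <- expand.grid(mu = mu_levels, sep = sep_levels,
                          noise_frac = noise_levels,
                          KEEP.OUT.ATTRS = FALSE)
  beta_levels <- c(0, 0.25, 0.5, 0.75, 1)
  out <- vector("list", nrow(settings) * reps)
  k <- 0L
  for (i in seq_len(nrow(settings))) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      seed <- (base_seed * 7919L + i * 131L + r) %% .Machine$integer.max
      set.seed(seed)
      mu <- settings$mu[i]
      H_a <- runif(1, 50, 150); H_b <- runif(1, 50, 150)
      s_a <- runif(1, 1, 4); s_b <- runif(1, 1, 4)
      th_a <- peak_params(H_a, 50, s_a, mu * s_a,
                          sample(beta_levels, 1), sample(beta_levels, 1))
      sep_u <- settings$sep[i] * (mu * s_a + s_b)
      th_b <- peak_params(H_b, 50 + sep_u, s_b, mu * s_b,
                          sample(beta_levels, 1), sample(beta_levels, 1))
      margin_lo <- 8 * s_a
      margin_hi <- 8 * mu * s_b
      out[[k]] <- data.frame(setting = i, rep = r, seed = seed,
                             mu = mu, sep = settings$sep[i],
                             noise_frac = settings$noise_frac[i],
                             noise_sd = settings$noise_frac[i] * H_a,
                             grid_start = 50 - margin_lo,
                             grid_stop = 50 + sep_u + margin_hi,
                             grid_by = 0.1)
      out[[k]]$theta_a <- list(th_a)
      out[[k]]$theta_b <- list(th_b)
    }
  }
  do.call(rbind, out)
}

#' Simulate a multi-peak MALDI-like spectrum
#'
#' Builds `n_peaks` mAPV components on `[mz_range[1], mz_range[2]]`
#' with random heights, widths and shapes, adds an exponentially
#' decaying baseline `baseline_amplitude * exp(-baseline_decay *
#' (m - m0))` and heteroscedastic Gaussian noise whose scale falls
#' linearly from `noise_sd_start` to `noise_sd_end` along the index
#' range (MALDI noise shrinks with m/z). Peak summits are kept at least
#' `min_spacing` half-width multiples apart so the truth is
#' well-defined.
#'
#' @param n_peaks number of true peaks.
#' @param mz_range numeric `c(lo, hi)` (u).
#' @param spacing grid spacing (u).
#' @param height_range,sigma_range uniform sampling ranges for `H` and
#'   the base half-width.
#' @param mu_max maximum per-peak asymmetry (sigma2/sigma1 drawn in
#'   `[1, mu_max]`).
#' @param baseline_amplitude,baseline_decay baseline parameters.
#' @param noise_sd_start,noise_sd_end noise scale at the first/last
#'   grid point.
#' @param min_spacing minimum summit separation in multiples of the
#'   larger neighbouring half-width.
#' @param seed RNG seed.
#' @return list with `spectrum` and `truth` as in
#'   [simulate_two_peak_spectrum()].
#' @export
simulate_multipeak_spectrum <- function(n_peaks = 30L,
                                        mz_range = c(100, 1100),
                                        spacing = 0.1,
                                        height_range = c(50, 300),
                                        sigma_range = c(0.8, 2.5),
                                        mu_max = 1.8,
                                        baseline_amplitude = 60,
                                        baseline_decay = 0.005,
                                        noise_sd_start = 4,
                                        noise_sd_end = 1,
                                        min_spacing = 6,
                                        seed = NULL) {
  stopifnot(n_peaks >= 0L, mz_range[2L] > mz_range[1L], spacing > 0,
            noise_sd_start >= 0, noise_sd_end >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- seq(mz_range[1L], mz_range[2L], by = spacing)
  margin <- 0.03 * (mz_range[2L] - mz_range[1L])
  thetas <- list()
  if (n_peaks > 0L) {
    alphas <- numeric(0)
    guard <- 0L
    while (length(alphas) < n_peaks && guard < 50L * n_peaks) {
      guard <- guard + 1L
      a <- runif(1, mz_range[1L] + margin, mz_range[2L] - margin)
      if (all(abs(a - alphas) > min_spacing * sigma_range[2L]))
        alphas <- c(alphas, a)
    }
    alphas <- sort(alphas)
    thetas <- lapply(alphas, function(a) {
      s1 <- runif(1, sigma_range[1L], sigma_range[2L])
      peak_params(runif(1, height_range[1L], height_range[2L]), a,
                  s1, runif(1, 1, mu_max) * s1,
                  runif(1), runif(1))
    })
  }
  y <- numeric(length(m))
  for (th in thetas) y <- y + mapv_eval(m, th)
  baseline <- baseline_amplitude *
    exp(-baseline_decay * (m - mz_range[1L]))
  noise_scale <- seq(noise_sd_start, noise_sd_end,
                     length.out = length(m))
  y <- y + baseline + rnorm(length(m), 0, 1) * noise_scale
  y <- pmax(y, 0)
  truth <- if (length(thetas)) truth_table(thetas, range(m))
           else peak_table()
  list(spectrum = mass_spectrum(m, y, list(stage = "simulated")),
       truth = truth)
}
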