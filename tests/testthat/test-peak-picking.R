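fast_hpso <- list(seed = 99, max_iter = 400, patience = 60)

test_that("valleys are located with plateau collapse and tolerance merge", {
  expect_equal(find_valleys(1:10), integer(0))
  expect_equal(find_valleys(c(0, 5, 1, 6, 0)), 3L)
  expect_equal(find_valleys(c(0, 5, 2, 2, 2, 6, 0)), 4L)  # plateau midpoint
  expect_equal(find_valleys(1:2), integer(0))
  # two dips separated by a barrier of 2.5: pruned at tolerance 2,
  # keeping the deeper valley
  y <- c(5, 1, 2.5, 2, 5)
  expect_equal(find_valleys(y, tolerance = 0), c(2L, 4L))
  expect_equal(find_valleys(y, tolerance = 2), 2L)
  # a lone shallow dip disappears once tolerance exceeds its prominence
  expect_equal(find_valleys(c(0, 5, 4, 6, 0), tolerance = 2), integer(0))
  expect_equal(find_valleys(c(0, 5, 4, 6, 0), tolerance = 0.5), 3L)
})

test_that("splitting shares valley points between components", {
  expect_equal(split_at_valleys(c(1, 2, 3)), list(1:3))
  comps <- split_at_valleys(c(0, 5, 1, 6, 0))
  expect_length(comps, 2L)
  expect_equal(comps[[1]], 1:3)
  expect_equal(comps[[2]], 3:5)
})

test_that("fit_component recovers a noiseless mAPV peak", {
  th <- theta_ref()
  m <- seq(500 - 8 * 2, 500 + 8 * 4, length.out = 100)
  y <- mapv_eval(m, th)
  fp <- fit_component(m, y, fast_hpso)
  expect_lt(fp$sse, 1e-4 * sum(y^2))
  expect_lt(abs(fp$theta[["alpha"]] - 500), diff(m)[1])
  expect_equal(fp$area, peak_area(fp$theta))
  expect_equal(fp$mu, asymmetry(fp$theta))
})

test_that("a symmetric Gaussian component fits as a symmetric near-Gaussian", {
  m <- seq(90, 110, length.out = 120)
  y <- gaussian_eval(m, 50, 100, 2.5)
  fp <- fit_component(m, y, fast_hpso)
  expect_lt(abs(fp$mu - 1), 0.1)
  expect_lt(fp$theta[["beta1"]], 0.15)
  expect_lt(fp$theta[["beta2"]], 0.15)
})

test_that("degenerate components are rejected", {
  expect_error(fit_component(c(1, 2, 3), c(0, 1, 0)), "insufficient")
  expect_error(fit_component(1:10, rep(0, 10)), "empty component")
})

test_that("a flat spectrum yields an empty peak table", {
  s <- mass_spectrum(1:100, rep(0, 100), list(stage = "baseline_corrected"))
  expect_equal(nrow(detect_peaks(s, hpso = fast_hpso)), 0L)
})

test_that("two separated peaks are detected within 1% m/z, deterministically", {
  set.seed(31)
  m <- seq(100, 200, by = 0.05)
  y <- mapv_eval(m, peak_params(100, 130, 2, 2.5, 0.2, 0.4)) +
       mapv_eval(m, peak_params(80, 170, 3, 3, 0.5, 0.5)) +
       rnorm(length(m), 0, 0.3)
  s <- preprocess_spectrum(mass_spectrum(m, pmax(y, 0)))
  # area threshold set as a user would for this noise level; the
  # automatic default errs toward sensitivity and admits ripple bumps
  cfg <- detector_config(area_threshold = 25)
  p1 <- detect_peaks(s, cfg, hpso = fast_hpso)
  p2 <- detect_peaks(s, cfg, hpso = fast_hpso)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 2L)
  expect_lt(abs(p1$summit_mz[1] - 130) / 130, 0.01)
  expect_lt(abs(p1$summit_mz[2] - 170) / 170, 0.01)
})

test_that("detected peaks respect the area threshold and their windows", {
  set.seed(32)
  sim <- simulate_multipeak_spectrum(n_peaks = 8, mz_range = c(100, 400),
                                     seed = 77)
  pre <- preprocess_spectrum(sim$spectrum)
  cfg <- detector_config(area_threshold = 30)
  tab <- detect_peaks(pre, cfg, fast_hpso)
  expect_true(all(tab$area >= 30))
  expect_true(all(tab$summit_mz >= tab$start_mz &
                  tab$summit_mz <= tab$end_mz))
  expect_true(!is.unsorted(tab$summit_mz))
})

test_that("asymmetric merged shoulder is re-split into two peaks", {
  # a sharp peak overlapping a broad one: the shallow inter-peak dip is
  # merged away by a large valley tolerance, so the single fit must
  # stretch sigma2 across the broad shoulder (mu > 2); the asymmetry
  # rule then re-splits at the hidden dip
  m <- seq(70, 150, by = 0.05)
  y <- gaussian_eval(m, 100, 100, 2) + gaussian_eval(m, 80, 108, 6)
  s <- mass_spectrum(m, y, list(stage = "baseline_corrected"))
  merged <- detect_peaks(s, detector_config(valley_tolerance = 100,
                                            asymmetry_threshold = 1e6),
                         fast_hpso)
  expect_equal(nrow(merged), 1L)  # split disabled: one asymmetric blob
  expect_gt(merged$asymmetry[1], 2)
  split <- detect_peaks(s, detector_config(valley_tolerance = 100),
                        fast_hpso)
  expect_equal(nrow(split), 2L)
  expect_lt(abs(split$summit_mz[1] - 100), 0.5)
  expect_lt(abs(split$summit_mz[2] - 108), 1)
})

test_that("unpreprocessed input triggers a warning but still runs", {
  m <- seq(1, 50, by = 0.5)
  s <- mass_spectrum(m, gaussian_eval(m, 10, 25, 2))
  expect_warning(tab <- detect_peaks(s, hpso = fast_hpso),
                 "preprocessed")
  expect_equal(nrow(tab), 1L)
})
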