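# noise estimation, SURE thresholding, smoothing, baseline

test_that("noise sigma estimator matches the MAD formula", {
  expect_equal(estimate_noise_sigma(rep(3, 10)), 0)
  expect_equal(estimate_noise_sigma(c(-1, 0, 1)), 1 / 0.6745)
  set.seed(21)
  x <- rnorm(1e5, sd = 2.5)
  expect_equal(estimate_noise_sigma(x), 2.5, tolerance = 0.02)
  expect_error(estimate_noise_sigma(numeric(1)), "at least 2")
})

test_that("sure_risk matches its closed-form endpoints and hand value", {
  set.seed(8)
  x <- rnorm(40, sd = 2)
  sigma <- 1.3
  d <- length(x)
  expect_equal(sure_risk(0, x, sigma), d * sigma^2)
  expect_equal(sure_risk(max(abs(x)) + 1, x, sigma),
               sum(x^2) - d * sigma^2)
  expect_equal(sure_risk(2, c(1, 3), 1), 5)
  expect_error(sure_risk(-1, x, sigma), "non-negative")
})

test_that("selected threshold matches a brute-force grid minimizer", {
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    sigma <- runif(1, 0.5, 2)
    t_sel <- select_sure_threshold(x, sigma)
    grid <- seq(0, max(abs(x)) * 1.2, length.out = 2000)
    r_grid <- vapply(grid, sure_risk, numeric(1), x = x, sigma = sigma)
    expect_lte(sure_risk(t_sel, x, sigma), min(r_grid) + 1e-10)
  }
})

test_that("SURE keeps strong coefficients and never beats identity on noise", {
  set.seed(10)
  x <- rnorm(100)
  t_noise <- select_sure_threshold(x, 1)
  expect_lte(sure_risk(t_noise, x, 1), sure_risk(0, x, 1))
  x_sig <- c(rnorm(100), rep(50, 5))
  t_sig <- select_sure_threshold(x_sig, 1)
  expect_true(all(abs(50) - t_sig > 0))  # big coefficients survive
})

test_that("baseline follows decreases and holds through increases", {
  s <- function(y) mass_spectrum(seq_along(y), y, allow_negative = TRUE)
  expect_equal(estimate_baseline(s(c(1, 2, 3, 4))), c(1, 1, 1, 1))
  expect_equal(estimate_baseline(s(c(4, 3, 2, 1))), c(4, 3, 2, 1))
  expect_equal(estimate_baseline(s(c(5, 3, 6, 2, 4))), c(5, 3, 3, 2, 2))
  set.seed(12)
  for (i in 1:20) {
    y <- rnorm(200)
    b <- estimate_baseline(s(y))
    expect_true(all(diff(b) <= 0))
    # hand recurrence oracle
    bb <- y[1]
    for (j in 2:length(y)) bb[j] <- min(bb[j - 1], y[j])
    expect_equal(b, bb)
  }
})

test_that("baseline correction subtracts, clips and checks lengths", {
  s <- mass_spectrum(1:5, c(5, 3, 6, 2, 4))
  b <- estimate_baseline(s)
  corrected <- correct_baseline(s, b)
  expect_equal(corrected$intensity, c(0, 0, 3, 0, 2))
  expect_equal(correct_baseline(s, rep(0, 5))$intensity, s$intensity)
  expect_equal(correct_baseline(s, s$intensity)$intensity, rep(0, 5))
  expect_error(correct_baseline(s, 1:3), "length")
  expect_true("baseline_corrected" %in% corrected$metadata$stage)
})

test_that("smoothing preserves zero input and reduces noise", {
  m <- seq(100, 200, by = 0.05)
  z <- smooth_spectrum(mass_spectrum(m, rep(0, length(m))))
  expect_equal(z$intensity, rep(0, length(m)))

  sig <- clean_two_gauss()
  set.seed(2)
  noisy <- sig$y + rnorm(length(sig$m), 0, 3)
  sm <- smooth_spectrum(mass_spectrum(sig$m, pmax(noisy, 0)))
  expect_lt(sqrt(mean((sm$intensity - sig$y)^2)),
            sqrt(mean((pmax(noisy, 0) - sig$y)^2)))
  expect_equal(length(sm), length(sig$m))
  expect_equal(sm$mz, sig$m)
})

test_that("smoothing a noiseless signal is close to a no-op", {
  sig <- clean_two_gauss()
  s1 <- smooth_spectrum(mass_spectrum(sig$m, sig$y))
  rel <- sqrt(sum((s1$intensity - sig$y)^2) / sum(sig$y^2))
  expect_lt(rel, 0.01)
})

test_that("smoothing quality is robust to small circular shifts", {
  sig <- clean_two_gauss()
  set.seed(5)
  noisy <- sig$y + rnorm(length(sig$y), 0, 3)
  rmse <- sapply(0:4, function(k) {
    xs <- c(noisy[(k + 1):length(noisy)], noisy[seq_len(k)])
    cs <- c(sig$y[(k + 1):length(sig$y)], sig$y[seq_len(k)])
    sm <- smooth_spectrum(mass_spectrum(sig$m, pmax(xs, 0)))
    sqrt(mean((sm$intensity - cs)^2))
  })
  expect_lt((max(rmse) - min(rmse)) / min(rmse), 0.15)
})

test_that("preprocessing preserves peaks of a clean separated spectrum", {
  sig <- clean_two_gauss()
  pre <- preprocess_spectrum(mass_spectrum(sig$m, sig$y))
  true_summits <- sig$m[c(which.max(gaussian_eval(sig$m, 100, 130, 2)),
                          which.max(gaussian_eval(sig$m, 80, 170, 3)))]
  vall <- find_valleys(pre$intensity)
  comps <- split_at_valleys(pre$intensity)
  big <- Filter(function(idx) max(pre$intensity[idx]) > 10, comps)
  expect_length(big, 2L)
  summits <- vapply(big, function(idx) sig$m[idx[which.max(pre$intensity[idx])]],
                    numeric(1))
  expect_equal(sort(summits), sort(true_summits), tolerance = 1e-3)
})

test_that("too-short spectra are rejected", {
  expect_error(smooth_spectrum(mass_spectrum(1:4, rep(1, 4)),
                               wavelet_config(n_segments = 4)),
               "too short")
})
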