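test_that("mAPV summit, half-height and hand-computed values are exact", {
  th <- theta_ref()
  expect_equal(mapv_eval(500, th), 100)
  for (b1 in c(0, 0.25, 0.5, 1)) for (b2 in c(0, 0.5, 0.75, 1)) {
    t2 <- peak_params(100, 500, 2, 4, b1, b2)
    expect_equal(mapv_eval(500 - 2, t2), 50)  # alpha - sigma1
    expect_equal(mapv_eval(500 + 4, t2), 50)  # alpha + sigma2
  }
  expect_equal(mapv_eval(497, th),
               100 * (0.3 / (1 + 2.25) + 0.7 * 2^(-2.25)),
               tolerance = 1e-12)
  expect_equal(round(mapv_eval(497, th), 2), 23.95)
})

test_that("mAPV degenerates exactly to the three comparison models", {
  set.seed(14)
  m <- seq(0, 1000, length.out = 2000)
  for (i in 1:20) {
    H <- runif(1, 1, 100); a <- runif(1, 100, 900)
    s1 <- runif(1, 0.5, 10); s2 <- runif(1, 0.5, 10)
    expect_equal(mapv_eval(m, peak_params(H, a, s1, s1, 0, 0)),
                 gaussian_eval(m, H, a, s1))
    expect_equal(mapv_eval(m, peak_params(H, a, s1, s1, 1, 1)),
                 lorentz_eval(m, H, a, s1))
    expect_equal(mapv_eval(m, peak_params(H, a, s1, s2, 0, 0)),
                 bigaussian_eval(m, H, a, s1, s2))
  }
})

test_that("mAPV is a proper unimodal peak", {
  set.seed(15)
  for (i in 1:10) {
    th <- random_theta()
    m <- seq(th[["alpha"]] - 20 * th[["sigma1"]],
             th[["alpha"]] + 20 * th[["sigma2"]], length.out = 999)
    v <- mapv_eval(m, th)
    expect_true(all(v >= 0))
    expect_true(all(v <= th[["H"]] + 1e-12))
    left <- v[m < th[["alpha"]]]
    right <- v[m >= th[["alpha"]]]
    expect_true(all(diff(left) >= -1e-12))
    expect_true(all(diff(right) <= 1e-12))
  }
})

test_that("analytic area matches closed forms and quadrature", {
  H <- 7; s <- 3
  expect_equal(peak_area(peak_params(H, 0, s, s, 1, 1)), H * s * pi)
  expect_equal(peak_area(peak_params(H, 0, s, s, 0, 0)),
               H * s * sqrt(pi / log(2)))
  set.seed(16)
  for (i in 1:20) {
    th <- random_theta()
    expect_equal(peak_area(th), quadrature_area(th), tolerance = 1e-6)
  }
})

test_that("asymmetry ratio behaves per its definition", {
  expect_equal(asymmetry(peak_params(1, 0, 3, 3, 0, 0)), 1)
  expect_equal(asymmetry(peak_params(1, 0, 2, 4, 0, 0)), 2)
  expect_equal(asymmetry(peak_params(1, 0, 4, 2, 0, 0)), 2)
})

test_that("invalid parameters are rejected", {
  expect_error(peak_params(-1, 0, 1, 1, 0, 0), "H")
  expect_error(peak_params(1, 0, 0, 1, 0, 0), "sigma")
  expect_error(peak_params(1, 0, 1, 1, -0.1, 0), "beta")
  expect_error(peak_params(1, 0, 1, 1, 0, 1.5), "beta")
})

test_that("compiled batch SSE agrees with direct R evaluation", {
  set.seed(17)
  m <- seq(480, 540, length.out = 137)
  y <- mapv_eval(m, theta_ref()) + rnorm(length(m))
  for (model in c("mapv", "gaussian", "lorentz", "bigaussian")) {
    d <- switch(model, gaussian = 3L, lorentz = 3L, bigaussian = 4L,
                mapv = 6L)
    Theta <- cbind(runif(25, 50, 150), runif(25, 480, 540),
                   runif(25, 0.5, 8), runif(25, 0.5, 8),
                   runif(25), runif(25))[, seq_len(d), drop = FALSE]
    ref <- apply(Theta, 1L, function(p) {
      v <- switch(model,
        mapv = mapv_eval(m, peak_params(p[1], p[2], p[3], p[4], p[5], p[6])),
        gaussian = gaussian_eval(m, p[1], p[2], p[3]),
        lorentz = lorentz_eval(m, p[1], p[2], p[3]),
        bigaussian = bigaussian_eval(m, p[1], p[2], p[3], p[4]))
      sum((v - y)^2)
    })
    expect_equal(mapvpeaks:::mapv_sse_batch(Theta, m, y, model), ref,
                 tolerance = 1e-12)
  }
})
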