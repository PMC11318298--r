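test_that("bi-exponential signal is 1 at b = 0, bounded in (0, 1], and non-increasing", {
  set.seed(1)
  for (i in 1:25) {
    p <- ivim_params(f = runif(1, 0, 0.5), Dstar = runif(1, 1.5e-3, 0.5),
                     D = runif(1, 0, 2.5e-3))
    b <- sort(c(0, runif(20, 0, 1500)))
    s <- ivim_signal(p, b)
    expect_identical(s[1], 1)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-15))
  }
})

test_that("signal matches direct scalar evaluation of the model", {
  # resting paraspinal-like values at the strongest diffusion weighting
  p <- ivim_params(0.11, 28.4e-3, 1.36e-3)
  expect_equal(ivim_signal(p, 700),
               0.11 * exp(-700 * 28.4e-3) + 0.89 * exp(-700 * 1.36e-3),
               tolerance = 1e-15)
  # mono-exponential limit
  p0 <- ivim_params(0, Dstar = 30e-3, D = 1.5e-3)
  expect_equal(ivim_signal(p0, 700), exp(-1.05), tolerance = 1e-15)
  b <- ivim_protocol_bvalues()
  expect_equal(ivim_signal(p0, b), mono_exp_signal(1, 1.5e-3, b),
               tolerance = 1e-15)
})

test_that("mono-exponential decay evaluates and validates as specified", {
  expect_equal(mono_exp_signal(1, 0, c(0, 100, 700)), rep(1, 3))
  expect_equal(mono_exp_signal(0.9, 1.5e-3, 0), 0.9)
  expect_equal(mono_exp_signal(0.89, 1.4e-3, 500), 0.89 * exp(-0.7),
               tolerance = 1e-15)
  expect_error(mono_exp_signal(0, 1e-3, 100), "positive")
  expect_error(mono_exp_signal(1, -1e-3, 100), "non-negative")
  expect_error(ivim_signal(ivim_params(0.1, 30e-3, 1e-3), -5), "non-negative")
})

test_that("residual norm is the squared L2 norm against the model", {
  p <- ivim_params(0.12, 32e-3, 1.3e-3)
  b <- ivim_protocol_bvalues()
  curve <- noiseless_curve(p$f, p$Dstar, p$D)
  expect_lt(residual_norm(curve, p), 1e-12)
  # single-point perturbation of +0.1 contributes exactly 0.01
  pert <- curve
  pert$signal[5] <- pert$signal[5] + 0.1
  expect_equal(residual_norm(pert, p), 0.01, tolerance = 1e-12)
  # brute-force elementwise loop oracle on a noisy curve
  set.seed(2)
  noisy <- noisy_curve(0.11, 28.4e-3, 1.36e-3, snr = 40)
  acc <- 0
  for (i in seq_along(b)) {
    m <- p$f * exp(-b[i] * p$Dstar) + (1 - p$f) * exp(-b[i] * p$D)
    acc <- acc + (noisy$signal[i] - m)^2
  }
  expect_equal(residual_norm(noisy, p), acc, tolerance = 1e-14)
  bad <- curve
  bad$signal <- bad$signal[-1]
  expect_error(residual_norm(bad, p), "mismatch")
})

test_that("parameter container recomputes fD* and rejects invalid values", {
  set.seed(3)
  for (i in 1:20) {
    f <- runif(1, 0, 0.5); ds <- runif(1, 1.5e-3, 0.5)
    p <- ivim_params(f, ds, runif(1, 0, 2.5e-3))
    expect_identical(p$fDstar, f * ds)
  }
  expect_error(ivim_params(-0.1, 30e-3, 1e-3), "non-negative")
  expect_error(ivim_params(0.1, Inf, 1e-3), "finite")
  expect_error(ivim_params(1.2, 30e-3, 1e-3), "exceed")
})

test_that("decay-curve construction normalizes and validates its inputs", {
  cv <- ivim_curve(c(0, 100, 700), c(200, 150, 60))
  expect_identical(cv$signal[1], 1)
  expect_equal(cv$signal, c(1, 0.75, 0.3))
  expect_error(ivim_curve(c(10, 100), c(1, 0.5)), "first b-value")
  expect_error(ivim_curve(c(0, 100, 100), c(1, 0.5, 0.4)), "increasing")
  expect_error(ivim_curve(c(0, 100), c(1, 0.5, 0.4)), "length")
  expect_error(ivim_curve(c(0, 100), c(0, 0.5)), "not positive")
})

test_that("constraint box validates intervals", {
  bnd <- ivim_bounds()
  # the D* floor sits above typical resting-muscle D (~1.4e-3 mm^2/s)
  expect_gt(bnd$Dstar_range[1], 1.4e-3)
  expect_error(ivim_bounds(f_range = c(0.5, 0)), "interval")
})
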