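# TAC fitting, piecewise TIA integration, hybrid rescaling, TIAC.

test_that("noiseless mono-exponential data are recovered exactly", {
  t <- c(24, 48, 96)
  x <- tac(t, 100 * exp(-0.02 * t))
  fit <- fit_monoexponential(x)
  expect_equal(fit$A0_MBq, 100, tolerance = 1e-7)
  expect_equal(fit$lambda_per_h, 0.02, tolerance = 1e-7)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("two-point fit is the exact interpolant", {
  fit <- fit_monoexponential(tac(c(24, 48), c(50, 25)))
  expect_equal(fit$lambda_per_h, log(2) / 24, tolerance = 1e-12)
  expect_equal(fit$A0_MBq, 100, tolerance = 1e-12)
})

test_that("weights do not matter at zero residual", {
  t <- c(24, 48, 96)
  x <- tac(t, 80 * exp(-0.01 * t))
  f1 <- fit_monoexponential(x, weights = "poisson")
  f2 <- fit_monoexponential(x, weights = "uniform")
  expect_equal(f1$lambda_per_h, f2$lambda_per_h, tolerance = 1e-7)
  expect_equal(f1$A0_MBq, f2$A0_MBq, tolerance = 1e-7)
})

test_that("implausibly slow decay is flagged", {
  x <- tac(c(24, 48, 96), 100 * exp(-0.002 * c(24, 48, 96)))
  expect_warning(fit <- fit_monoexponential(x), "physical decay")
  expect_true(fit$flag_slow_decay)
  expect_error(fit_monoexponential(tac(c(24, 48), c(0, 0))), "positive")
})

test_that("constant activity integrates to the rectangle-trapezoid-tail
           closed form", {
  lam <- lu177_lambda()
  a <- 40
  x <- tac(c(24, 48, 96), rep(a, 3))
  fit <- suppressWarnings(fit_monoexponential(
    tac(c(24, 48, 96), a * exp(-1e-4 * c(24, 48, 96)))))
  expect_equal(integrate_tia(x), a * 96 + a / lam, tolerance = 1e-12)
  expect_equal(integrate_tia(tac(c(24, 48, 96), c(0, 0, 0))), 0)
})

test_that("piecewise integral matches the hand-derived value at pure
           physical decay", {
  # frozen from the analytic evaluation of the scheme: rectangle under-
  # estimates the rising early integral by more than the trapezoids
  # overestimate, so the piecewise TIA is 0.99556 of A0/lambda
  lam <- lu177_lambda()
  t <- c(24, 48, 96)
  x <- tac(t, 100 * exp(-lam * t))
  tia <- integrate_tia(x)
  expect_equal(tia / (100 / lam), 0.9955608, tolerance = 1e-6)
})

test_that("physical-decay tail overestimates TIA under biological
           clearance; fitted tail does not", {
  lam <- lu177_lambda()
  t <- c(24, 48, 96)
  x <- tac(t, 100 * exp(-5 * lam * t))
  fit <- fit_monoexponential(x)
  analytic <- 100 / (5 * lam)
  # frozen from the analytic evaluation: +42.6% with the physical tail
  expect_equal(integrate_tia(x) / analytic, 1.4259289, tolerance = 1e-5)
  # fitted tail stays within a few percent (rectangle underestimate)
  expect_lt(abs(integrate_tia(x, fit, tail = "fit") / analytic - 1),
            0.08)
})

test_that("trapezoidal segment is exact for piecewise-linear activity", {
  t <- c(24, 30, 48, 72, 96)
  a <- c(10, 9, 6, 4, 1)
  x <- tac(t, a)
  lam <- lu177_lambda()
  manual <- a[1] * t[1] + sum((a[-1] + a[-5]) / 2 * diff(t)) + a[5] / lam
  expect_equal(integrate_tia(x), manual, tolerance = 1e-12)
})

test_that("the tail vanishes for fast physical decay", {
  fast <- physical_decay(100)
  x <- tac(c(24, 48, 96), c(10, 5, 2))
  expect_equal(integrate_tia(x, decay = fast),
               10 * 24 + sum(c(7.5 * 24, 3.5 * 48)) + 2 / 100,
               tolerance = 1e-12)
})

test_that("hybrid rescaling preserves curve shape and fitted lambda", {
  t <- c(24, 48, 96)
  planar <- tac(t, c(100, 50, 20), method = "2D", region = "kidneys")
  hy <- hybrid_rescale(planar, 120, 24)
  expect_equal(hy$activities_MBq, c(120, 60, 24))
  expect_identical(hy$method, "hybrid")
  f1 <- suppressWarnings(fit_monoexponential(planar))
  f2 <- suppressWarnings(fit_monoexponential(hy))
  expect_equal(f1$lambda_per_h, f2$lambda_per_h, tolerance = 1e-5)
  # identity when SPECT equals planar at the anchor
  expect_equal(hybrid_rescale(planar, 100, 24)$activities_MBq,
               planar$activities_MBq)
  expect_error(hybrid_rescale(planar, 120, 60), "anchor")
})

test_that("hybrid rescaling corrects a multiplicative planar bias", {
  # planar biased low by a constant factor (overlap), SPECT unbiased:
  # the hybrid TIA must be closer to truth than the planar TIA in at
  # least 95% of noisy replicates
  set.seed(11)
  lam <- 2 * lu177_lambda()
  t <- c(24, 48, 96)
  truth_tia <- integrate_tia(tac(t, 100 * exp(-lam * t)))
  wins <- replicate(400, {
    bias <- exp(rnorm(1, -0.15, 0.05))
    a2d <- 100 * exp(-lam * t) * bias * exp(rnorm(3, 0, 0.03))
    a3d1 <- 100 * exp(-lam * 24) * exp(rnorm(1, 0, 0.03))
    planar <- tac(t, a2d, method = "2D")
    hy <- hybrid_rescale(planar, a3d1, 24)
    abs(integrate_tia(hy) - truth_tia) <=
      abs(integrate_tia(planar) - truth_tia)
  })
  expect_gte(mean(wins), 0.95)
})

test_that("TIAC is TIA per administered activity in hours", {
  expect_equal(compute_tiac(6400, 6.4), 1)
  expect_equal(compute_tiac(0, 6.4), 0)
  expect_equal(compute_tiac(6400, 12.8), 0.5)
})

test_that("TAC validation rejects malformed curves", {
  expect_error(tac(c(48, 24), c(1, 2)))
  expect_error(tac(c(24, 48), c(1, -2)))
  expect_error(tac(c(24, 48), c(1, 2), weights = c(1, 0)))
})
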