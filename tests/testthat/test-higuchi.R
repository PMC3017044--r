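test_that("per-offset curve length matches hand-computed values", {
  # linear ramp: sum of unit increments, normalization gives exactly N-1
  expect_equal(curve_length(0:4, k = 1, m = 1), 4)
  # constant series has zero length at every admissible (k, m)
  const <- rep(3.7, 9)
  for (k in 1:4) for (m in seq_len(k))
    expect_identical(curve_length(const, k, m), 0)
  # alternating series sampled at every 2nd point is constant
  expect_identical(curve_length(c(0, 1, 0, 1, 0, 1, 0, 1, 0), k = 2, m = 1), 0)
})

test_that("curve length preconditions name the offending parameter", {
  expect_error(curve_length(0:4, k = 2, m = 3), "'m'")
  expect_error(curve_length(0:4, k = 5, m = 1), "'k'")
  expect_error(curve_length(0:4, k = 0, m = 1), "'k'")
  expect_error(mean_curve_length(0:4, k = 3), "maximum admissible k")
  expect_error(curve_length(c(1, NA, 3), 1, 1), "finite")
  expect_error(curve_length(numeric(1), 1, 1), "at least 2")
})

test_that("mean curve length matches hand computation and the ramp law", {
  # ramp of length 9: L(k) = (N-1)/k when k divides N-1
  expect_equal(mean_curve_length(0:8, 1), 8)
  expect_equal(mean_curve_length(0:8, 2), 4)
  expect_equal(mean_curve_length(0:8, 4), 2)
  # length-5 series, k = 2, by hand:
  # L_1(2) over (3,4,5)=(x1,x3,x5): (|4-3|+|5-4|) * 4/(2*2) / 2 = 1
  # L_2(2) over (1,1)=(x2,x4): 0 -> mean 0.5
  expect_equal(mean_curve_length(c(3, 1, 4, 1, 5), 2), 0.5)
})

test_that("mean curve length agrees exactly with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(5:64, 1)
    x <- rand_series(n)
    for (k in seq_len((n - 1) %/% 2)) {
      expect_equal(mean_curve_length(x, k), naive_mean_curve_length(x, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("fractal dimension is invariant under affine amplitude maps", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rand_series(sample(64:256, 1))
    a <- stats::runif(1, -5, 5)
    if (abs(a) < 0.1) a <- 1
    c0 <- stats::runif(1, -100, 100)
    expect_equal(higuchi(a * x + c0)$df, higuchi(x)$df, tolerance = 1e-9)
  }
  # the specific transform x -> 1000 x + 7
  x <- rand_series(512)
  expect_lt(abs(higuchi(1000 * x + 7)$df - higuchi(x)$df), 1e-9)
})

test_that("smooth curves estimate near dimension 1", {
  th <- seq(0, 2 * pi, length.out = 1024)
  expect_lt(abs(higuchi(sin(th), kmax = 8)$df - 1), 0.05)
  expect_lt(abs(higuchi(th^2, kmax = 8)$df - 1), 0.05)
})

test_that("L(k) decays monotonically on rough series", {
  for (s in 1:5) {
    fit <- higuchi(gen_fbm(1024, 0.5, seed = s), kmax = 8)
    expect_true(all(diff(fit$lengths) <= 0))
  }
})

test_that("degenerate series raise errors instead of returning a dimension", {
  expect_error(higuchi(rep(1, 100)), "degenerate")
  # period-2 series: L(2) = 0
  expect_error(higuchi(rep(c(0, 1), 50), kmax = 2), "degenerate")
  expect_error(higuchi(rand_series(10), kmax = 5), "inadmissible")
  expect_error(higuchi(rand_series(100), kmax = 1), "at least 2")
})

test_that("default kmax follows the documented rule", {
  expect_identical(default_kmax(128), 8L)
  expect_identical(default_kmax(4096), 8L)
  expect_identical(default_kmax(100), 8L)   # floor(99/2) capped at 8
  expect_identical(default_kmax(10), 4L)
  expect_identical(default_kmax(5), 2L)
})

test_that("higuchi model methods are mutually consistent", {
  x <- gen_fbm(512, 0.5, seed = 3)
  fit <- higuchi(x, kmax = 8)
  expect_s3_class(fit, "higuchi")
  expect_named(coef(fit), c("df", "intercept"))
  expect_length(fit$lengths, 8)
  expect_true(all(fit$lengths > 0))
  expect_true(fit$fit_r2 > 0.9 && fit$fit_r2 <= 1)
  # residuals + fitted reproduce the observed log-lengths
  expect_equal(log(fitted(fit)) + residuals(fit), fit$logl)
  # predict at the fitted k equals fitted()
  expect_equal(predict(fit), fitted(fit))
  expect_error(predict(fit, k = -1), "positive")
  expect_output(print(fit), "D_f")
  s <- summary(fit)
  expect_equal(nrow(s$table), 8)
  expect_output(print(s), "log_L|log_k|D_f")
})
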