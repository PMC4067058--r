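test_that("scale update is the weighted least-squares gain, gauge-fixed", {
  set.seed(20)
  # self-consistent slice: scale 1
  y <- runif(50, 10, 20)
  up <- update_scales(y, y, rep(1, 50), rep(0, 50), rep(1L, 50), 1)
  expect_equal(up$raw[1], 1)
  expect_equal(up$scales[1], 1)
  # slice = 2 x simulation: raw gain 0.5 before renormalization
  up2 <- update_scales(2 * y, y, rep(1, 50), rep(0, 50), rep(1L, 50), 1)
  expect_equal(up2$raw[1], 0.5)

  # random instance against the direct sums
  n <- 200
  y <- runif(n, 1, 30)
  yh <- runif(n, 1, 30)
  p <- runif(n)
  b <- rnorm(n, 0, 0.05)
  sl <- sample(1:4, n, replace = TRUE)
  up3 <- update_scales(y, yh, p, b, sl, 4)
  for (k in 1:4) {
    sel <- sl == k
    expected <- sum(p[sel] * exp(-b[sel]) * y[sel] * yh[sel]) /
      sum(p[sel] * (exp(-b[sel]) * y[sel])^2)
    expect_lt(abs(up3$raw[k] - expected), 1e-12)
  }
  expect_lt(abs(prod(up3$scales) - 1), 1e-9)
})

test_that("degenerate slices keep their previous scale", {
  y <- c(runif(20), rep(0, 10))
  yh <- c(runif(20), runif(10))
  sl <- rep(1:2, c(20, 10))
  expect_warning(
    up <- update_scales(y, yh, rep(c(1, 0), c(20, 10)), rep(0, 30), sl, 2,
                        prev_scales = c(1, 0.8)),
    "degenerate")
  expect_equal(up$raw[2], 0.8)
})

make_test_slice <- function(n = 24, spacing = 1) {
  g <- image_grid(c(n, n, 1L), c(spacing, spacing, 3))
  vals <- matrix(runif(n * n, 40, 60), n, n)
  mri_slice(vals, g, 3)
}

test_that("bias update leaves zero residuals alone and kills constants", {
  set.seed(21)
  sl <- make_test_slice()
  p1 <- matrix(1, 24, 24)
  s2 <- update_bias(sl, sl$values, p1, bias_settings(sigma = 5))
  expect_lt(max(abs(s2$bias)), 1e-12)

  # constant residual: smoothing returns the constant, the zero-mean
  # constraint removes it entirely (a constant log-offset is a scale)
  sim <- sl$values * exp(-0.2)
  s3 <- update_bias(sl, sim, p1, bias_settings(sigma = 5))
  expect_lt(max(abs(s3$bias)), 1e-9)
})

test_that("bias update recovers a smooth synthetic bias field", {
  set.seed(22)
  n <- 32
  g <- image_grid(c(n, n, 1L), c(1, 1, 3))
  base <- matrix(runif(n * n, 40, 60), n, n)
  xs <- (seq_len(n) - (n + 1) / 2) / n
  true_b <- 0.15 * outer(sin(2 * xs), cos(2 * xs))
  true_b <- true_b - mean(true_b)
  sl <- mri_slice(base * exp(true_b), g, 3)  # y = exp(b) * truth
  p1 <- matrix(1, n, n)
  for (i in 1:30) sl <- update_bias(sl, base, p1, bias_settings(sigma = 8))
  err <- sqrt(mean((sl$bias - true_b)^2))
  expect_lt(err, 0.3 * sqrt(mean(true_b^2)))
  expect_lt(abs(mean(sl$bias)), 1e-9)
})

test_that("objective is non-increasing under a scale update", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 120
    y <- runif(n, 5, 40)
    yh <- runif(n, 5, 40)
    p <- runif(n)
    b <- rnorm(n, 0, 0.1)
    sl <- sample(1:3, n, replace = TRUE)
    ps <- runif(3)
    s0 <- rep(1, 3)
    f0 <- svrsr:::intensity_objective(y, yh, p, ps, b, s0, sl)
    up <- update_scales(y, yh, p * ps[sl], b, sl, 3, s0)
    f1 <- svrsr:::intensity_objective(y, yh, p, ps, b, up$raw, sl)
    expect_lte(f1, f0 + 1e-9)
  }
})
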