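test_that("voxel posteriors follow the mixture formula", {
  m <- voxel_robust_model(sigma2 = 1, c = 0.9, m = 0.01)
  e <- c(0, 0.5, -2, 10)
  g <- exp(-e^2 / 2) / sqrt(2 * pi)
  expect_lt(max(abs(voxel_posteriors(e, m) -
                      g * 0.9 / (g * 0.9 + 0.01 * 0.1))), 1e-12)
  # limits
  expect_equal(voxel_posteriors(e, voxel_robust_model(1, 1, 0.01)),
               rep(1, 4))
  expect_equal(voxel_posteriors(e, voxel_robust_model(1, 0, 0.01)),
               rep(0, 4))
  # monotone non-increasing in |e|
  e2 <- seq(0, 50, by = 0.25)
  p <- voxel_posteriors(e2, m)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("influence function is redescending", {
  m <- voxel_robust_model(sigma2 = 2, c = 0.8, m = 0.05)
  e <- seq(0, 500, by = 1)
  infl <- e * voxel_posteriors(e, m)
  expect_lt(infl[length(infl)], 1e-6)
  peak <- which.max(infl)
  expect_true(all(diff(infl[peak:length(infl)]) <= 1e-12))
})

test_that("M-step updates are the posterior-weighted moments", {
  set.seed(10)
  e <- rnorm(500)
  m0 <- voxel_robust_model(1, 0.5, 0.1)
  up <- update_voxel_model(e, rep(1, 500), m0)
  expect_equal(up$sigma2, mean(e^2))
  expect_equal(up$c, 1)
  expect_equal(up$m, m0$m)

  p <- runif(500)
  up2 <- update_voxel_model(e, p, m0)
  expect_lt(abs(up2$sigma2 - sum(p * e^2) / sum(p)), 1e-12)
  expect_lt(abs(up2$c - sum(p) / 500), 1e-12)

  # degenerate zero-error inliers hit the variance floor
  e3 <- c(rep(0, 10), rep(5, 10))
  p3 <- c(rep(1, 10), rep(0, 10))
  up3 <- update_voxel_model(e3, p3, m0, intensity_scale = 100)
  expect_equal(up3$sigma2, (1e-6 * 100)^2)
  expect_equal(up3$c, 0.5)
  expect_error(update_voxel_model(e3, rep(0, 20), m0), "degenerate")
})

test_that("EM iterations never decrease the observed-data log-likelihood", {
  set.seed(11)
  e <- c(rnorm(400, 0, 2), runif(100, -30, 30))
  model <- voxel_robust_model(mean(e^2), 0.9, init_uniform_density(e))
  ll_old <- svrsr:::voxel_loglik(e, model)
  for (i in 1:20) {
    p <- voxel_posteriors(e, model)
    model <- update_voxel_model(e, p, model)
    ll <- svrsr:::voxel_loglik(e, model)
    expect_gte(ll, ll_old - 1e-8)
    ll_old <- ll
  }
})

test_that("uniform density comes from the error range", {
  expect_equal(init_uniform_density(c(-2, 0, 3)), 0.2)
  expect_equal(init_uniform_density(rep(1.5, 10)), 1e6)
  set.seed(12)
  e <- rnorm(100)
  expect_equal(init_uniform_density(e), 1 / diff(range(e)))
  expect_error(init_uniform_density(numeric(0)), "empty")
})

test_that("slice potentials are normalized sums of squared posteriors", {
  p <- c(rep(1, 4), rep(0, 3), 0.5, 0.25)
  sl <- c(1, 1, 1, 1, 2, 2, 2, 3, 3)
  pot <- suppressWarnings(slice_potentials(p, sl, 4))
  expect_equal(pot[1], 1)
  expect_equal(pot[2], 0)
  expect_lt(abs(pot[3] - (0.25 + 0.0625) / 2), 1e-12)
  expect_warning(slice_potentials(p, sl, 4), "no in-mask")
  expect_true(is.na(suppressWarnings(slice_potentials(p, sl, 4))[4]))
})

test_that("two-Gaussian slice classification separates clear clusters", {
  set.seed(13)
  pot <- c(rnorm(20, 0.1, 0.01), rnorm(20, 0.9, 0.01))
  post <- slice_posteriors(pot)
  expect_true(all(post[1:20] < 0.01))
  expect_true(all(post[21:40] > 0.99))
  # larger-mean rule with one slice per cluster
  expect_equal(slice_posteriors(c(0, 1)), c(0, 1), tolerance = 1e-6)
  # identical potentials: nothing to classify
  expect_equal(slice_posteriors(rep(0.7, 10)), rep(1, 10))
})

test_that("huber weights match the piecewise formula", {
  expect_equal(huber_weights(c(0.5, -1, 2), gamma = 1), c(1, 1, 0.5))
  # default gamma = 1.35 * median|e|
  w <- huber_weights(c(1, -2, 3))
  expect_equal(w, c(1, 1, 2.7 / 3))
  # continuity at |e| = gamma
  eps <- 1e-9
  expect_lt(abs(huber_weights(1 + eps, gamma = 1) -
                  huber_weights(1 - eps, gamma = 1)), 1e-8)
  expect_error(huber_weights(1:3, gamma = 0), "positive")
})
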