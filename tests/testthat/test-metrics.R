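test_that("nrmse and psnr follow their definitions", {
  g <- image_grid(c(4, 4, 4), c(1, 1, 1))
  a <- volume3d(array(2, c(4, 4, 4)), g)
  b <- volume3d(array(3, c(4, 4, 4)), g)
  expect_equal(nrmse(a, a), 0)
  expect_equal(nrmse(b, a), 0.5)

  set.seed(30)
  x <- volume3d(array(runif(64, 1, 10), c(4, 4, 4)), g)
  y <- volume3d(array(runif(64, 1, 10), c(4, 4, 4)), g)
  direct <- sqrt(mean((x$values - y$values)^2)) / mean(y$values)
  expect_lt(abs(nrmse(x, y) - direct), 1e-12)

  # psnr decades
  mx <- max(y$values)
  rmse <- sqrt(mean((x$values - y$values)^2))
  expect_lt(abs(psnr(x, y) - 20 * log10(mx / rmse)), 1e-9)
  z <- volume3d(y$values - mx, g)   # rmse exactly MAX
  expect_lt(abs(psnr(z, y) - 0), 1e-9)
  expect_equal(psnr(y, y), Inf)
  expect_error(nrmse(x, volume3d(array(0, c(4, 4, 4)), g)), "zero")
})

test_that("nrmse respects the evaluation mask", {
  g <- image_grid(c(4, 4, 4), c(1, 1, 1))
  ref <- array(2, c(4, 4, 4))
  rec <- ref
  rec[1, 1, 1] <- 10
  msk <- array(TRUE, c(4, 4, 4))
  msk[1, 1, 1] <- FALSE
  expect_equal(nrmse(rec, ref, msk), 0)
  expect_gt(nrmse(rec, ref), 0)
})

test_that("tre matches per-point distances and the exclusion rules", {
  set.seed(31)
  pts <- replicate(4, matrix(runif(180, -20, 20), 60, 3), simplify = FALSE)
  truth <- replicate(4, random_rigid(), simplify = FALSE)
  est <- truth
  expect_equal(tre(est, truth, pts)$mean_mm, 0)

  est[[2]] <- compose(rigid_transform(diag(3), c(3, 0, 0)), truth[[2]])
  r <- tre(est, truth, pts)
  expect_lt(abs(r$per_slice[2] - 3), 1e-9)

  # brute-force oracle on random rotations
  est2 <- lapply(truth, function(tf)
    compose(euler_transform(runif(1, -2, 2), runif(1, -2, 2),
                            runif(1, -2, 2), runif(1, -1, 1), 0, 0), tf))
  r2 <- tre(est2, truth, pts)
  manual <- mean(unlist(lapply(1:4, function(k)
    sqrt(rowSums((apply_transform(est2[[k]], pts[[k]]) -
                    apply_transform(truth[[k]], pts[[k]]))^2)))))
  expect_lt(abs(r2$mean_mm - manual), 1e-9)

  # exclusions: corrupted/displaced labels and small ROI
  labels <- c("clean", "corrupted", "displaced", "clean")
  pts[[4]] <- pts[[4]][1:10, , drop = FALSE]   # below min_roi
  r3 <- tre(est2, truth, pts, labels)
  expect_equal(which(r3$included), 1L)
  expect_error(tre(est2, truth, pts, rep("corrupted", 4)), "no included")
})

test_that("tre is gauge invariant under a common rigid transform", {
  set.seed(32)
  pts <- replicate(3, matrix(runif(180, -15, 15), 60, 3), simplify = FALSE)
  truth <- replicate(3, random_rigid(), simplify = FALSE)
  est <- lapply(truth, function(tf)
    compose(euler_transform(1, -1, 0.5, 0.3, -0.2, 0.1), tf))
  G <- random_rigid()
  r1 <- tre(est, truth, pts)
  r2 <- tre(lapply(est, function(tf) compose(G, tf)),
            lapply(truth, function(tf) compose(G, tf)), pts)
  expect_lt(abs(r1$mean_mm - r2$mean_mm), 1e-9)
})

test_that("gauge_align removes a common rigid misalignment", {
  set.seed(33)
  pts <- replicate(3, matrix(runif(180, -15, 15), 60, 3), simplify = FALSE)
  truth <- replicate(3, random_rigid(), simplify = FALSE)
  G <- euler_transform(4, -3, 2, 5, -4, 3)
  est <- lapply(truth, function(tf) compose(G, tf))
  expect_gt(tre(est, truth, pts)$mean_mm, 1)
  fixed <- gauge_align(est, truth, pts)
  expect_lt(tre(fixed, truth, pts)$mean_mm, 1e-6)
})

test_that("leave-one-out returns the noise floor for a perfect volume", {
  sim <- tiny_sim()
  ph <- tiny_phantom()
  # held-out stack regenerated noise-free and corruption-free, with truth
  spec0 <- simulation_spec(n_stacks = 1, thickness = 3, inplane = 1.5,
                           seed = 41, noise_fraction = 0.02,
                           bias_amplitude = 0, scale_range = c(1, 1),
                           n_displaced = 0, n_corrupted = 0,
                           max_rotation = 0, max_translation = 0)
  s1 <- simulate_acquisition(ph, spec0)
  held <- transfer_mask(s1$stacks, ph)[[1]]
  loo <- leave_one_out(ph, held, register = FALSE,
                       bias = bias_settings(enabled = FALSE))
  # the residual is exactly the added noise: sigma = 0.02 x the same
  # masked mean that normalizes the metric, so nrmse ~ 0.02
  expect_lt(abs(loo$nrmse - 0.02) / 0.02, 0.25)
  # ssd non-increasing across alternations
  expect_true(all(diff(loo$ssd_trace) <= 1e-6 * loo$ssd_trace[1]))
})
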