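test_that("gaussian-weighted initialization averages corrected intensities", {
  g <- image_grid(c(16, 16, 16), c(1, 1, 1))
  st <- flat_stack(g, function(n1, n2, z) matrix(4.5, n1, n2))
  M <- build_system_matrix(st, g)
  y <- rep(4.5, nrow(M$M))
  init <- gaussian_weighted_init(M, y)
  covered <- init$weights > 0
  expect_lt(max(abs(init$volume$values[covered] - 4.5)), 1e-9)
  # uncovered voxels are flagged and inpainted, not zeroed
  if (any(init$uncovered))
    expect_true(all(abs(init$volume$values[init$uncovered] - 4.5) < 1e-9))
})

test_that("gaussian init equals the dense weighted mean", {
  set.seed(40)
  g <- image_grid(c(10, 10, 8), c(1, 1, 1))
  st <- flat_stack(g, function(n1, n2, z) matrix(runif(n1 * n2), n1, n2),
                   thickness = 2, z_positions = c(1.5, 3.5, 5.5))
  M <- build_system_matrix(st, g)
  y <- svrsr:::extract_rows(svrsr:::all_slices(st), M$rows, "values")
  init <- gaussian_weighted_init(M, y)
  dense <- as.matrix(M$M)
  num <- colSums(dense * y)
  den <- colSums(dense)
  expect_lt(max(abs(init$volume$values[den > 0] -
                      (num / den)[den > 0])), 1e-10)
})

test_that("regularizer gradient matches finite differences of R(X)", {
  set.seed(41)
  x <- array(runif(5 * 5 * 5, 0, 10), c(5, 5, 5))
  delta <- 2
  D <- regularizer_gradient(x, delta)
  # D is the descent direction: dR/dx = -4 * delta^2 ... / see docs
  h <- 1e-5
  idx <- cbind(c(2, 3, 1, 5, 4), c(2, 1, 4, 5, 3), c(3, 2, 1, 5, 4))
  for (r in seq_len(nrow(idx))) {
    xp <- x; xm <- x
    xp[idx[r, 1], idx[r, 2], idx[r, 3]] <- xp[idx[r, 1], idx[r, 2], idx[r, 3]] + h
    xm[idx[r, 1], idx[r, 2], idx[r, 3]] <- xm[idx[r, 1], idx[r, 2], idx[r, 3]] - h
    num <- (svrsr:::regularizer_value(xp, delta) -
              svrsr:::regularizer_value(xm, delta)) / (2 * h)
    ana <- -4 * D[idx[r, 1], idx[r, 2], idx[r, 3]]
    expect_lt(abs(num - ana) / max(abs(num), 1e-8), 1e-5)
  }
  # constant volume: no edges, no gradient
  expect_equal(max(abs(regularizer_gradient(array(3, c(4, 4, 4)), 1))), 0)
})

test_that("b_id weights equal 1/|d| at zero difference", {
  nb <- svrsr:::neighbor_offsets()
  x <- array(5, c(3, 3, 3))
  # all differences zero: gradient contribution zero but weights well-defined
  for (q in c(1, 5, 14)[c(1, 2)]) {
    len <- nb$len[q]
    b <- 1 / (len * sqrt(1 + 0))
    expect_equal(b, 1 / len)
  }
})

test_that("sr_update reduces to the classical gradient step", {
  set.seed(42)
  g <- image_grid(c(10, 10, 8), c(1, 1, 1))
  st <- flat_stack(g, function(n1, n2, z) matrix(runif(n1 * n2), n1, n2),
                   thickness = 2, z_positions = c(1.5, 3.5, 5.5))
  M <- build_system_matrix(st, g)
  x <- runif(ncol(M$M))
  y <- svrsr:::extract_rows(svrsr:::all_slices(st), M$rows, "values")
  e <- y - as.vector(M$M %*% x)
  n_sl <- length(st$slices)
  s <- recon_settings(alpha = 0.3, lambda_factor = 0, delta = 1,
                      step_mode = "global")
  # all weights one, lambda 0: x + alpha * t(M) e exactly (Eq. 4 data term)
  upd <- sr_update(x, M, e, rep(1, length(e)), rep(1, n_sl), s)
  expect_lt(max(abs(upd$x - (x + 0.3 * as.vector(Matrix::t(M$M) %*% e)))),
            1e-12)
  # zero errors: fixed point
  upd0 <- sr_update(x, M, rep(0, length(e)), rep(1, length(e)),
                    rep(1, n_sl), s)
  expect_equal(upd0$x, x)

  # robust-weighted update against a literal dense implementation
  p <- runif(length(e))
  ps <- runif(n_sl)
  upd2 <- sr_update(x, M, e, p, ps, s)
  dense <- as.matrix(M$M)
  lit <- x + 0.3 * colSums(dense * (ps[M$rows$slice] * p * e))
  expect_lt(max(abs(upd2$x - lit)), 1e-10)
})

test_that("confidence-weighted smoothing is a stable convex blend", {
  set.seed(43)
  x <- array(runif(6 * 6 * 6, 0, 10), c(6, 6, 6))
  conf <- array(runif(length(x)), dim(x))
  sm <- svrsr:::edge_smooth(x, conf, k = 0.5, delta = 2)
  expect_true(all(sm >= min(x) - 1e-12 & sm <= max(x) + 1e-12))
  # k = 0: identity
  expect_equal(svrsr:::edge_smooth(x, conf, 0, 2), x)
  # zero-confidence voxel is inpainted from neighbors
  conf2 <- conf
  conf2[3, 3, 3] <- 0
  x2 <- x
  x2[3, 3, 3] <- 1e3   # an outlier value with no data support
  sm2 <- svrsr:::edge_smooth(x2, conf2, 0.5, 2)
  expect_lt(sm2[3, 3, 3], 15)
})

test_that("delta defaults to half the dominant tissue mode distance", {
  set.seed(44)
  v <- c(rnorm(4000, 45, 1.5), rnorm(4000, 62, 1.5))
  d <- estimate_delta(v)
  expect_lt(abs(d - 8.5), 1.5)
  # degenerate: constant intensities
  expect_equal(estimate_delta(rep(5, 100)), 1)
})

test_that("reconstruction improves on the initialization and monitors the objective", {
  sim <- tiny_sim()
  ph <- tiny_phantom()
  # corruption-free stacks with known transforms
  spec <- simulation_spec(n_stacks = 3, thickness = 3, inplane = 1.5,
                          seed = 10, noise_fraction = 0.01,
                          bias_amplitude = 0, scale_range = c(1, 1),
                          n_displaced = 0, n_corrupted = 0)
  s0 <- simulate_acquisition(ph, spec)
  stacks <- transfer_mask(apply_true_transforms(s0$stacks, s0$truth), ph)
  M <- build_system_matrix(stacks, ph$grid)
  y <- svrsr:::extract_rows(svrsr:::all_slices(stacks), M$rows, "values")
  init <- gaussian_weighted_init(M, y)
  res <- reconstruct(stacks, ph$grid,
                     recon_settings(em_iterations = 5, lambda_factor = 0.01,
                                    use_robust = "none",
                                    use_intensity_matching = FALSE))
  msk <- ph$mask
  err_init <- nrmse(init$volume$values, ph$values, msk)
  err_final <- nrmse(res$volume$values, ph$values, msk)
  expect_lt(err_final, err_init)
  # data term decreases across EM iterations in this benign setting
  expect_true(all(diff(res$objective) < 0))
})

test_that("reconstruction state is written back to the slices", {
  sim <- tiny_sim()
  res <- reconstruct(sim$stacks_true, tiny_phantom()$grid,
                     recon_settings(em_iterations = 2, lambda_factor = 0.01))
  slices <- svrsr:::all_slices(res$stacks)
  sc <- vapply(slices, `[[`, numeric(1), "scale")
  expect_lt(abs(prod(sc) - 1), 1e-9)
  for (sl in slices[1:5]) {
    expect_true(all(sl$posteriors >= 0 & sl$posteriors <= 1))
    if (any(sl$mask)) expect_lt(abs(mean(sl$bias[sl$mask])), 1e-9)
  }
  expect_equal(res$diagnostics$excluded,
               res$diagnostics$slice_posterior < 0.5)
})
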