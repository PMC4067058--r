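test_that("NMI behaves like a similarity measure should", {
  set.seed(50)
  a <- rnorm(5000)
  expect_lt(abs(nmi(a, a, 32) - 2), 1e-12)
  expect_lt(abs(nmi(a, sample(a), 32) - 1), 0.05)
  b <- rnorm(5000)
  expect_lt(abs(nmi(a, b, 32) - nmi(b, a, 32)), 1e-12)
  # invariance to positive affine intensity mapping (exact: same binning)
  expect_lt(abs(nmi(a, 3.7 * b + 11, 32) - nmi(a, b, 32)), 1e-12)
  expect_error(nmi(NA_real_, 1), "overlap")
})

test_that("slice registration recovers a known pose and respects guards", {
  sim <- tiny_sim()
  ph <- tiny_phantom()
  # reconstruction from true transforms as the registration target
  res <- reconstruct(sim$stacks_true, ph$grid,
                     recon_settings(em_iterations = 5, lambda_factor = 0.01))
  vol <- res$volume
  # central slice of the axial stack, perturbed by 2 mm / 2 deg
  slices <- svrsr:::all_slices(sim$stacks_true)
  nvox <- vapply(slices, function(s) sum(s$mask), integer(1))
  sl <- slices[[which.max(nvox)]]
  truthT <- sl$transform
  ctr <- colMeans(slice_points(sl))
  sl$transform <- compose(
    svrsr:::centered_transform(2, -1, 1, c(1.2, -1, 0.8), ctr), truthT)
  fit <- register_slice_to_volume(sl, vol, registration_settings(bins = 32))
  pts <- slice_points(sl, transform = rigid_transform())
  err <- mean(sqrt(rowSums((apply_transform(fit$transform, pts) -
                              apply_transform(truthT, pts))^2)))
  expect_lt(err, 1)
  expect_false(fit$flagged)

  # starting at the truth stays near the truth
  sl$transform <- truthT
  fit2 <- register_slice_to_volume(sl, vol, registration_settings(bins = 32))
  err2 <- mean(sqrt(rowSums((apply_transform(fit2$transform, pts) -
                               apply_transform(truthT, pts))^2)))
  expect_lt(err2, 0.8)

  # constant slice: flagged, transform unchanged
  slc <- sl
  slc$values[] <- 5
  fit3 <- register_slice_to_volume(slc, vol)
  expect_true(fit3$flagged)
  expect_identical(fit3$transform, slc$transform)

  # too few in-mask voxels: flagged
  sls <- sl
  sls$mask[] <- FALSE
  sls$mask[1:10] <- TRUE
  expect_true(register_slice_to_volume(sls, vol)$flagged)
})

test_that("stack registration recovers identity and right-angle poses", {
  ph <- tiny_phantom()
  fit <- register_stack_to_template(ph, ph, registration_settings(bins = 32))
  pr <- transform_params(fit$transform)
  expect_lt(max(abs(pr[4:6])), 0.5)
  expect_lt(max(abs(pr[1:3])), 1)
  expect_gt(fit$overlap, 0.9)

  # 90-degree rotated copy: the multi-start must find its way back
  ctr <- c(0, 0, 0)
  G <- svrsr:::centered_transform(90, 0, 0, c(0, 0, 0), ctr)
  rot <- volume3d(array(interpolate_volume(ph, apply_transform(
    G, grid_points(ph$grid)), outside = 0), ph$grid$shape), ph$grid)
  fit2 <- register_stack_to_template(rot, ph, registration_settings(bins = 32))
  # the rotated image holds ph(G(x)), so the template point p matches the
  # moving-image point G^-1(p)
  pts <- grid_points(ph$grid)[as.vector(ph$mask), ][seq(1, sum(ph$mask), 40), ]
  d <- sqrt(rowSums((apply_transform(fit2$transform, pts) -
                       apply_transform(invert(G), pts))^2))
  expect_lt(mean(d), 1.5)

  # disjoint volumes: failure diagnostic
  far <- ph
  far$grid <- image_grid(ph$grid$shape, ph$grid$spacing,
                         origin = ph$grid$origin + 500)
  expect_error(register_stack_to_template(far, ph), "overlap")
})
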