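test_that("phantom generation is deterministic and brain-like", {
  p1 <- make_phantom(36, 1.5, seed = 7)
  p2 <- make_phantom(36, 1.5, seed = 7)
  expect_identical(p1$values, p2$values)
  expect_false(identical(p1$values,
                         make_phantom(36, 1.5, seed = 8)$values))
  expect_true(all(p1$values >= 0) && max(p1$values) <= 110)

  # >= 3 tissue modes in the smoothed in-mask histogram
  v <- p1$values[p1$mask]
  dens <- density(v, n = 512)
  pk <- which(dens$y > c(dens$y[-1], -Inf) &
                dens$y > c(-Inf, dens$y[-length(dens$y)]) &
                dens$y > 0.05 * max(dens$y))
  expect_gte(length(pk), 3)

  # head mask is one connected component
  lab <- svrsr:::connected_components3d(p1$mask)
  expect_equal(max(lab), 1L)
  expect_error(make_phantom(-10), "positive")
})

test_that("corruption-free acquisition equals the forward model exactly", {
  ph <- tiny_phantom()
  spec <- simulation_spec(n_stacks = 1, thickness = 3, inplane = 1.5,
                          seed = 5, noise_fraction = 0, bias_amplitude = 0,
                          scale_range = c(1, 1), n_displaced = 0,
                          n_corrupted = 0, max_rotation = 0,
                          max_translation = 0)
  sim <- simulate_acquisition(ph, spec)
  st <- sim$stacks[[1]]
  M <- build_system_matrix(st, ph$grid, mask_only = FALSE)
  yhat <- simulate_slices(ph, M)
  yhat[is.na(yhat)] <- 0
  y <- unlist(lapply(st$slices, function(s) as.vector(s$values)))
  ord <- order(M$rows$slice, M$rows$pixel)
  expect_lt(max(abs(y - yhat[ord])), 1e-12)
  expect_true(all(sim$truth$labels == "clean"))
  expect_true(all(vapply(sim$truth$transforms, is_identity_transform,
                         logical(1), tol = 1e-12)))
})

test_that("intensity corruption draws respect the stated protocol", {
  sim <- tiny_sim()
  truth <- sim$truth
  expect_true(all(truth$scales >= 0.8 & truth$scales <= 1.2))
  expect_equal(sort(unique(truth$labels)),
               sort(c("clean", "corrupted", "displaced")))
  expect_equal(sum(truth$labels == "displaced"), 2)
  expect_equal(sum(truth$labels == "corrupted"), 2)

  # bias fields: zero mean over support and smooth at the 12 mm scale
  ph <- tiny_phantom()
  mid <- which.max(vapply(truth$biases, function(b) sum(abs(b)), numeric(1)))
  b <- truth$biases[[mid]]
  supp <- truth$clean_values[[mid]] > 0.05 * mean(ph$values[ph$mask])
  expect_lt(abs(mean(b[supp])), 1e-9)
  # lag-h in-plane autocorrelation at h = sigma_B stays high
  h <- round(12 / 1.5)
  v1 <- as.vector(b[1:(nrow(b) - h), ])
  v2 <- as.vector(b[(1 + h):nrow(b), ])
  expect_gt(cor(v1, v2), 0.5)
})

test_that("acquisition is reproducible and sub-seeds are independent", {
  ph <- tiny_phantom()
  spec <- simulation_spec(n_stacks = 1, thickness = 3, inplane = 1.5,
                          seed = 33, n_displaced = 1, n_corrupted = 1)
  s1 <- simulate_acquisition(ph, spec)
  s2 <- simulate_acquisition(ph, spec)
  expect_identical(s1$stacks[[1]]$slices[[5]]$values,
                   s2$stacks[[1]]$slices[[5]]$values)
  expect_identical(s1$truth$labels, s2$truth$labels)

  # disabling intensity corruption must not change the motion draw
  spec_clean <- spec
  spec_clean$bias_amplitude <- 0
  spec_clean$scale_range <- c(1, 1)
  s3 <- simulate_acquisition(ph, spec_clean)
  expect_identical(s1$truth$labels, s3$truth$labels)
  for (k in seq_along(s1$truth$transforms))
    expect_lt(max(abs(as_matrix4(s1$truth$transforms[[k]]) -
                        as_matrix4(s3$truth$transforms[[k]]))), 1e-12)
})

test_that("displaced slices move beyond the registration capture range", {
  sim <- tiny_sim()
  truth <- sim$truth
  slices <- svrsr:::all_slices(sim$stacks)
  for (g in which(truth$labels == "displaced")) {
    pts <- slice_points(slices[[g]], mask_only = FALSE)
    moved <- apply_transform(truth$transforms[[g]], pts)
    # nominal (undisplaced) positions are within a few mm of identity
    expect_gt(mean(sqrt(rowSums((moved - pts)^2))), 10)
  }
  # clean slices move by the small-motion magnitudes only
  for (g in utils::head(which(truth$labels == "clean"), 5)) {
    pts <- slice_points(slices[[g]], mask_only = FALSE)
    moved <- apply_transform(truth$transforms[[g]], pts)
    expect_lt(mean(sqrt(rowSums((moved - pts)^2))), 6)
  }
})

test_that("requesting more outliers than slices errors", {
  ph <- tiny_phantom()
  spec <- simulation_spec(n_stacks = 1, slices_per_stack = 4,
                          thickness = 3, inplane = 1.5,
                          n_displaced = 10, n_corrupted = 10, seed = 1)
  expect_error(simulate_acquisition(ph, spec), "outlier")
})
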