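test_that("default PSF follows the slice geometry", {
  p <- default_psf(3, 1)
  expect_equal(p$fwhm, c(1.2, 1.2, 3))
  expect_equal(p$sigma, p$fwhm / (2 * sqrt(2 * log(2))))
  # thin-slice protocol: 1.176 mm in-plane, 2.5 mm thick
  p2 <- default_psf(2.5, 1.176)
  expect_equal(p2$fwhm, c(1.4112, 1.4112, 2.5))
  expect_error(default_psf(0, 1), "positive")
  expect_error(default_psf(3, -1), "positive")
})

make_grid20 <- function() image_grid(c(20, 20, 20), c(1, 1, 1))

test_that("delta-function limit hits the nearest voxel with weight 1", {
  g <- make_grid20()
  sg <- image_grid(c(3, 3, 1), c(1, 1, 3), origin = c(9.2, 8.9, 10.4))
  st <- slice_stack(list(mri_slice(matrix(1, 3, 3), sg, 3)), 1, 3)
  M <- build_system_matrix(st, g, psf = psf_spec(1e-4, 1e-4, 1e-4))
  expect_true(all(Matrix::rowSums(M$M != 0) == 1))
  expect_true(all(abs(M$M@x - 1) < 1e-12))
  # nearest-voxel positions: rounding of the world coordinates
  tm <- methods::as(M$M, "TsparseMatrix")
  j <- (tm@j + 1L)[order(tm@i)]
  exp_first <- round(9.2) + 20 * round(8.9) + 400 * round(10.4) + 1
  expect_equal(j[1], exp_first)
})

test_that("row normalization reproduces constants and rows are stochastic", {
  g <- make_grid20()
  st <- flat_stack(g, function(n1, n2, z) matrix(0, n1, n2))
  M <- build_system_matrix(st, g)
  rs <- Matrix::rowSums(M$M)
  expect_true(all(abs(rs[!M$empty] - 1) < 1e-6))
  expect_true(all(M$M@x >= 0))
  vol <- volume3d(array(7.5, g$shape), g)
  expect_true(all(abs(simulate_slices(vol, M) - 7.5) < 1e-9, na.rm = TRUE))
  expect_true(all(simulate_slices(volume3d(array(0, g$shape), g), M) == 0,
                  na.rm = TRUE))
})

test_that("oblique PSF rows match a dense brute-force Gaussian", {
  g <- make_grid20()
  tf <- euler_transform(10, -7, 22, 1.5, -2, 0.7)
  sg <- image_grid(c(1, 1, 1), c(1, 1, 3), origin = c(9.5, 9.5, 9.5))
  s1 <- mri_slice(matrix(1, 1, 1), sg, 3, tf)
  M <- build_system_matrix(slice_stack(list(s1), 1, 3), g)
  psf <- default_psf(3, 1)
  p <- slice_points(s1)
  axes <- tf$R %*% sg$direction
  u <- sweep(grid_points(g), 2, as.numeric(p)) %*% axes
  w <- exp(-0.5 * rowSums(sweep(u, 2, psf$sigma, `/`)^2))
  w[apply(abs(u) > matrix(3 * psf$sigma, nrow(u), 3, byrow = TRUE), 1, any)] <- 0
  expect_lt(max(abs(as.vector(M$M[1, ]) - w / sum(w))), 1e-9)
})

test_that("simulation agrees with a dense matrix-vector product", {
  set.seed(6)
  g <- image_grid(c(8, 8, 8), c(1, 1, 1))
  st <- flat_stack(g, function(n1, n2, z) matrix(0, n1, n2), thickness = 2,
                   z_positions = c(1, 3, 5))
  M <- build_system_matrix(st, g)
  x <- runif(prod(g$shape))
  dense <- as.matrix(M$M)
  expect_lt(max(abs(simulate_slices(x, M) - as.vector(dense %*% x)),
                na.rm = TRUE), 1e-12)
})

test_that("forward and adjoint are consistent", {
  set.seed(7)
  g <- make_grid20()
  st <- flat_stack(g, function(n1, n2, z) matrix(0, n1, n2))
  M <- build_system_matrix(st, g)
  x <- rnorm(ncol(M$M))
  y <- rnorm(nrow(M$M))
  expect_lt(abs(sum((M$M %*% x) * y) - sum(x * (Matrix::t(M$M) %*% y))),
            1e-10)
})

test_that("simulated values are equivariant under a common rigid motion", {
  g <- image_grid(c(12, 12, 12), c(1.5, 1.5, 1.5))
  set.seed(8)
  vol_vals <- array(runif(prod(g$shape)), g$shape)
  tf_slice <- euler_transform(5, -3, 8, 1, 0.5, -1)
  sg <- image_grid(c(6, 6, 1), c(1.5, 1.5, 3), origin = c(3, 3, 8))
  sl <- mri_slice(matrix(0, 6, 6), sg, 3, tf_slice)
  M1 <- build_system_matrix(slice_stack(list(sl), 1.5, 3), g)
  y1 <- as.vector(M1$M %*% as.vector(vol_vals))

  G <- euler_transform(17, 9, -25, 4, -6, 2)
  g2 <- image_grid(g$shape, g$spacing,
                   origin = apply_transform(G, g$origin),
                   direction = G$R %*% g$direction)
  sl2 <- sl
  sl2$transform <- compose(G, tf_slice)
  M2 <- build_system_matrix(slice_stack(list(sl2), 1.5, 3), g2)
  y2 <- as.vector(M2$M %*% as.vector(vol_vals))
  expect_lt(max(abs(y1 - y2)), 1e-9)
})

test_that("system matrix triplet dump round-trips", {
  g <- image_grid(c(8, 8, 8), c(1, 1, 1))
  st <- flat_stack(g, function(n1, n2, z) matrix(0, n1, n2), thickness = 2,
                   z_positions = c(2, 4))
  M <- build_system_matrix(st, g)
  f <- withr::local_tempfile(fileext = ".csv")
  dump_system_matrix(M, f)
  tr <- utils::read.csv(f)
  M2 <- Matrix::sparseMatrix(i = tr$row, j = tr$col, x = tr$value,
                             dims = dim(M$M))
  expect_lt(max(abs(M2 - M$M)), 1e-15)
})
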