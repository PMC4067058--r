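# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code at a reduced phantom scale so the whole suite stays
# within its time budget; the corruption protocol itself (slice
# thickness, noise fraction, bias smoothness, scale range, outlier
# counts per three stacks) is never scaled.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# small phantom used by most pipeline tests (36 mm head, 1.5 mm voxels)
tiny_phantom <- function() memo("tiny_phantom", make_phantom(36, 1.5, seed = 4))

# mid-size phantom at the acquisition protocol's native 1 mm resolution
small_phantom <- function() memo("small_phantom", make_phantom(48, 1, seed = 4))

random_rigid <- function() {
  euler_transform(runif(1, -180, 180), runif(1, -90, 90),
                  runif(1, -180, 180), runif(1, -20, 20),
                  runif(1, -20, 20), runif(1, -20, 20))
}

random_grid <- function() {
  R <- random_rigid()$R
  image_grid(sample(3:8, 3, replace = TRUE), runif(3, 0.5, 3),
             origin = runif(3, -10, 10), direction = R)
}

# one axial stack of constant-geometry slices over a grid, no motion
flat_stack <- function(grid, values_fun, thickness = 3, n1 = NULL, n2 = NULL,
                       z_positions = NULL) {
  if (is.null(n1)) n1 <- grid$shape[1]
  if (is.null(n2)) n2 <- grid$shape[2]
  if (is.null(z_positions))
    z_positions <- seq(1, grid$shape[3] * grid$spacing[3] - 1, by = thickness)
  slices <- lapply(z_positions, function(z) {
    sg <- image_grid(c(n1, n2, 1L), c(grid$spacing[1:2], thickness),
                     origin = grid$origin + c(0, 0, z))
    mri_slice(values_fun(n1, n2, z), sg, thickness)
  })
  slice_stack(slices, grid$spacing[1], thickness)
}

# corrupted-world simulation shared by robust/superres tests
tiny_sim <- function() memo("tiny_sim", {
  ph <- tiny_phantom()
  spec <- simulation_spec(n_stacks = 3, thickness = 3, inplane = 1.5,
                          seed = 9, n_displaced = 2, n_corrupted = 2)
  sim <- simulate_acquisition(ph, spec)
  sim$stacks_masked <- transfer_mask(sim$stacks, ph)
  sim$stacks_true <- transfer_mask(apply_true_transforms(sim$stacks, sim$truth), ph)
  sim
})
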