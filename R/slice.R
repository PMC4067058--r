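#' A single acquired 2D slice
#'
#' A slice is a 2D intensity array embedded in 3D world space.  Its own
#' `grid` (shape `c(n1, n2, 1)`) places in-plane voxel centers in world
#' space according to the stack geometry; the `transform` is the current
#' estimate of the slice's rigid motion, applied *after* the grid mapping,
#' so the world position of slice voxel `(j1, j2)` is
#' `transform(voxel_to_world(grid, c(j1, j2, 0)))`.  The slice normal
#' (through-plane PSF axis) is the third column of
#' `transform$R %*% grid$direction`.
#'
#' Intensity state estimated during reconstruction lives on the slice as
#' well: multiplicative scale `scale` (s_k), log-domain differential bias
#' field `bias` (b_jk, same 2D shape), voxel inlier posteriors
#' `posteriors` (p_jk), slice inlier posterior `slice_posterior`
#' (p_k^slice) and the hard `excluded` flag reported when
#' `slice_posterior < 0.5`.  Corrected intensities are always
#' `scale * exp(-bias) * values`.
#'
#' @param values n1 x n2 numeric matrix of acquired intensities.
#' @param grid [image_grid()] with shape `c(n1, n2, 1)`; its spacing is
#'   `c(inplane, inplane, thickness)`.
#' @param thickness slice thickness in mm (through-plane PSF FWHM source).
#' @param transform current [rigid_transform()] motion estimate.
#' @param mask logical n1 x n2 matrix of in-mask voxels.
#' @return An object of class `mri_slice`.
#' @export
mri_slice <- function(values, grid, thickness,
                      transform = rigid_transform(), mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(all(dim(mask) == dim(values)),
            all(grid$shape == c(dim(values), 1L)))
  structure(list(values = values, mask = as.matrix(mask), grid = grid,
                 thickness = as.numeric(thickness), transform = transform,
                 scale = 1, bias = matrix(0, nrow(values), ncol(values)),
                 posteriors = matrix(1, nrow(values), ncol(values)),
                 slice_posterior = 1, excluded = FALSE),
            class = "mri_slice")
}

#' Scaled and bias-corrected slice intensities
#'
#' `y* = s * exp(-b) * y`: the acquisition model ties the corrected slice
#' to the volume through the system matrix.
#'
#' @param slice an [mri_slice()].
#' @return Numeric matrix of corrected intensities.
#' @export
corrected_values <- function(slice) {
  slice$scale * exp(-slice$bias) * slice$values
}

#' World coordinates of slice voxel centers
#'
#' @param slice an [mri_slice()].
#' @param mask_only if TRUE (default) only in-mask voxels, in column-major
#'   order of the slice array.
#' @param transform transform to apply on top of the slice grid; defaults
#'   to the slice's current motion estimate.
#' @return n x 3 matrix of world mm.
#' @export
slice_points <- function(slice, mask_only = TRUE, transform = slice$transform) {
  d <- dim(slice$values)
  idx <- as.matrix(expand.grid(seq_len(d[1]) - 1L, seq_len(d[2]) - 1L))
  if (mask_only) idx <- idx[as.vector(slice$mask), , drop = FALSE]
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0L, 3L))
  base <- voxel_to_world(slice$grid, cbind(idx, 0))
  apply_transform(transform, base)
}

#' A stack of parallel slices
#'
#' All slices in a stack share in-plane spacing and thickness; the stack
#' `pose` is the stack-level transform obtained from volumetric
#' pre-registration (slices inherit it as the starting point of their own
#' motion estimates).
#'
#' @param slices list of [mri_slice()] objects.
#' @param inplane in-plane spacing in mm (scalar or length 2).
#' @param thickness slice thickness in mm.
#' @param pose stack-level [rigid_transform()].
#' @param orientation free-text acquisition direction label.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, inplane, thickness,
                        pose = rigid_transform(), orientation = "") {
  stopifnot(length(slices) >= 1L)
  th <- vapply(slices, `[[`, numeric(1), "thickness")
  if (max(abs(th - thickness)) > 1e-9)
    stop("all slices in a stack must share the slice thickness")
  structure(list(slices = slices,
                 inplane = rep(as.numeric(inplane), length.out = 2L),
                 thickness = as.numeric(thickness), pose = pose,
                 orientation = orientation),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]]$values)
  cat(sprintf("slice_stack '%s': %d slices of %d x %d, %.3g mm in-plane, %.3g mm thick\n",
              x$orientation, length(x$slices), d[1], d[2],
              x$inplane[1], x$thickness))
  invisible(x)
}

# Normalize the "stacks" argument accepted throughout the package: a single
# slice_stack or a list of them.
as_stack_list <- function(stacks) {
  if (inherits(stacks, "slice_stack")) list(stacks) else {
    stopifnot(all(vapply(stacks, inherits, logical(1), "slice_stack")))
    stacks
  }
}

# Flat per-voxel table over all in-mask voxels of all slices: the engine's
# working representation.  Columns refer to global slice ids (order of
# stacks, then slices within stack).
stack_table <- function(stacks) {
  stacks <- as_stack_list(stacks)
  ys <- list(); sl <- list(); px <- list()
  info <- list()
  s_id <- 0L
  for (si in seq_along(stacks)) {
    st <- stacks[[si]]
    for (k in seq_along(st$slices)) {
      s_id <- s_id + 1L
      sk <- st$slices[[k]]
      keep <- which(as.vector(sk$mask))
      ys[[s_id]] <- as.vector(sk$values)[keep]
      sl[[s_id]] <- rep.int(s_id, length(keep))
      px[[s_id]] <- keep
      info[[s_id]] <- data.frame(stack = si, k = k, n = length(keep))
    }
  }
  list(y = unlist(ys), slice = unlist(sl), pixel = unlist(px),
       info = do.call(rbind, info), n_slices = s_id)
}

# Run a function over every slice of every stack, replacing the slice by
# its return value.  f(slice, global_slice_id) -> slice.
map_slices <- function(stacks, f) {
  stacks <- as_stack_list(stacks)
  s_id <- 0L
  for (si in seq_along(stacks)) {
    for (k in seq_along(stacks[[si]]$slices)) {
      s_id <- s_id + 1L
      stacks[[si]]$slices[[k]] <- f(stacks[[si]]$slices[[k]], s_id)
    }
  }
  stacks
}

# Flat list of all slices (global slice id order).
all_slices <- function(stacks) {
  stacks <- as_stack_list(stacks)
  do.call(c, lapply(stacks, `[[`, "slices"))
}
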