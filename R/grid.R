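#' World-anchored image grid
#'
#' An `image_grid` describes a regular voxel lattice embedded in world
#' (scanner) space in millimetres.  Voxel indices are zero-based and refer
#' to voxel *centers*: index `(0,0,0)` maps to `origin`.  The mapping is
#' the affine `world = origin + direction %*% (spacing * index)` with an
#' orthonormal `direction` matrix (columns are the world directions of the
#' voxel axes), so it is exactly invertible.
#'
#' @param shape integer vector of length 3, voxels per axis (>= 1).
#' @param spacing numeric vector of length 3, voxel size in mm (> 0).
#' @param origin world coordinates (mm) of the center of voxel (0,0,0).
#' @param direction 3x3 orthonormal direction-cosine matrix.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, spacing, origin = c(0, 0, 0),
                       direction = diag(3)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values")
  direction <- as.matrix(direction)
  if (!is_orthonormal(direction))
    stop("'direction' must be orthonormal (|det| = 1)")
  structure(list(shape = shape, spacing = spacing,
                 origin = as.numeric(origin), direction = direction),
            class = "image_grid")
}

is_orthonormal <- function(R, tol = 1e-9) {
  all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < 1e-6 &&
    abs(abs(det(R)) - 1) < tol
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(x$shape, collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = "/"),
      "mm\n  origin", paste(signif(x$origin, 4), collapse = ", "), "mm\n")
  invisible(x)
}

#' Map voxel indices to world coordinates
#'
#' Indices may be fractional and may lie outside the grid; the map is the
#' affine voxel-center convention of [image_grid()].
#'
#' @param grid an [image_grid()].
#' @param index numeric vector of length 3 or an n x 3 matrix of
#'   zero-based (possibly fractional) voxel indices.
#' @return World coordinates in mm, same shape as `index`.
#' @export
voxel_to_world <- function(grid, index) {
  idx <- to_points(index)
  w <- sweep(idx, 2L, grid$spacing, `*`) %*% t(grid$direction)
  w <- sweep(w, 2L, grid$origin, `+`)
  shape_like(w, index)
}

#' Map world coordinates to continuous voxel indices
#'
#' Exact inverse of [voxel_to_world()].
#'
#' @inheritParams voxel_to_world
#' @param world numeric length-3 vector or n x 3 matrix of world mm.
#' @return Continuous zero-based voxel indices.
#' @export
world_to_voxel <- function(grid, world) {
  p <- to_points(world)
  q <- sweep(p, 2L, grid$origin, `-`) %*% grid$direction  # R^T = R^-1
  q <- sweep(q, 2L, grid$spacing, `/`)
  shape_like(q, world)
}

to_points <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    x
  } else {
    stopifnot(length(x) == 3L)
    matrix(as.numeric(x), 1L, 3L)
  }
}

shape_like <- function(m, template) {
  if (is.matrix(template)) m else drop(m)
}

#' All voxel centers of a grid in world coordinates
#'
#' @param grid an [image_grid()].
#' @return An N x 3 matrix (N = prod(shape)) in column-major voxel order,
#'   matching the storage order of volume arrays.
#' @export
grid_points <- function(grid) {
  idx <- as.matrix(expand.grid(
    x = seq_len(grid$shape[1]) - 1L,
    y = seq_len(grid$shape[2]) - 1L,
    z = seq_len(grid$shape[3]) - 1L))
  voxel_to_world(grid, idx)
}
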