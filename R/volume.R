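#' Scalar 3D volume on a world-anchored grid
#'
#' The reconstruction target and all 3D images (phantoms, masks as logical
#' volumes) are `volume3d` objects: a 3D array of intensities plus an
#' [image_grid()] and an optional logical mask of the region of interest.
#'
#' @param values 3D numeric array.
#' @param grid an [image_grid()] whose shape matches `dim(values)`.
#' @param mask optional logical array of the same shape.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, grid, mask = NULL) {
  values <- as.array(values)
  if (!all(dim(values) == grid$shape))
    stop("value array shape does not match grid shape")
  if (any(!is.finite(values)))
    stop("volume values must be finite")
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(values))
    if (!all(dim(mask) == grid$shape))
      stop("mask shape does not match grid shape")
  }
  structure(list(values = values, grid = grid, mask = mask),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("volume3d:", paste(dim(x$values), collapse = " x "),
      sprintf("voxels, range [%.4g, %.4g]%s\n",
              min(x$values), max(x$values),
              if (is.null(x$mask)) "" else
                sprintf(", mask %d voxels", sum(x$mask))))
  invisible(x)
}

#' Logical mask of a volume (all-TRUE when absent)
#' @param vol a [volume3d()].
#' @return Logical array of the volume's shape.
#' @export
volume_mask <- function(vol) {
  if (is.null(vol$mask)) array(TRUE, dim = dim(vol$values)) else vol$mask
}

#' Trilinear interpolation of a volume at world points
#'
#' @param vol a [volume3d()].
#' @param points n x 3 matrix of world coordinates (mm).
#' @param outside value returned for points outside the grid (default NA).
#' @return Numeric vector of interpolated intensities.
#' @export
interpolate_volume <- function(vol, points, outside = NA_real_) {
  idx <- world_to_voxel(vol$grid, to_points(points))
  trilinear_cpp(vol$values, idx, as.numeric(outside))
}
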