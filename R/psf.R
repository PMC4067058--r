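#' Gaussian point-spread-function specification
#'
#' The acquisition PSF is modeled as an anisotropic 3D Gaussian aligned
#' with the slice frame: the in-plane profile approximates the main lobe
#' of the sinc excitation (FWHM = 1.2 x in-plane voxel size) and the
#' through-plane profile is the slice profile (FWHM = slice thickness).
#' `sigma = FWHM / (2 sqrt(2 log 2))` per axis.  The kernel is truncated
#' at `truncation` sigmas per axis (default 3, losing < 0.3% of mass).
#'
#' @param fwhm_inplane_x,fwhm_inplane_y in-plane FWHM in mm.
#' @param fwhm_throughplane through-plane FWHM in mm.
#' @param truncation truncation radius in sigma units.
#' @return An object of class `psf_spec`.
#' @export
psf_spec <- function(fwhm_inplane_x, fwhm_inplane_y, fwhm_throughplane,
                     truncation = 3) {
  fwhm <- c(fwhm_inplane_x, fwhm_inplane_y, fwhm_throughplane)
  if (any(!is.finite(fwhm)) || any(fwhm <= 0))
    stop("PSF FWHM values must be positive")
  if (truncation <= 0) stop("'truncation' must be positive")
  structure(list(fwhm = fwhm, sigma = fwhm / (2 * sqrt(2 * log(2))),
                 truncation = truncation),
            class = "psf_spec")
}

#' Default PSF for a slice geometry
#'
#' FWHM = slice thickness through-plane and 1.2 x voxel size in-plane.
#'
#' @param slice_thickness slice thickness in mm.
#' @param inplane_spacing in-plane voxel size in mm (scalar or length 2).
#' @param truncation truncation radius in sigma units.
#' @return A [psf_spec()].
#' @export
default_psf <- function(slice_thickness, inplane_spacing, truncation = 3) {
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("'slice_thickness' must be positive")
  if (any(!is.finite(inplane_spacing)) || any(inplane_spacing <= 0))
    stop("'inplane_spacing' must be positive")
  ip <- rep(inplane_spacing, length.out = 2L)
  psf_spec(1.2 * ip[1], 1.2 * ip[2], slice_thickness, truncation)
}

#' @export
print.psf_spec <- function(x, ...) {
  cat(sprintf("psf_spec: FWHM (%.4g, %.4g, %.4g) mm, truncation %g sigma\n",
              x$fwhm[1], x$fwhm[2], x$fwhm[3], x$truncation))
  invisible(x)
}

#' Sparse system matrix linking a volume to acquired slices
#'
#' Builds the forward model `y_hat = M x`: one row per in-mask slice
#' voxel, holding the discretized oriented PSF — a Gaussian kernel
#' centered at the slice voxel's world position, axes rotated by the
#' slice transform, evaluated at the volume's voxel centers inside the
#' truncation box and then normalized to sum 1.  Row normalization makes
#' the forward model have unit gain, so a constant volume simulates to
#' exactly that constant and per-slice scales remain identifiable.
#'
#' Rows whose PSF support lies entirely outside `grid` are empty and
#' flagged in `$empty`.
#'
#' @param stacks a [slice_stack()] or list of stacks.
#' @param grid the reconstruction [image_grid()].
#' @param psf a [psf_spec()]; default derived per stack via
#'   [default_psf()] from its thickness and in-plane spacing.
#' @param mask_only use only in-mask slice voxels (default TRUE).
#' @return An object of class `system_matrix`: `M` (dgCMatrix, rows x
#'   volume voxels), `rows` (data.frame: global slice id, within-slice
#'   pixel index), `empty` (logical per row), `grid`.
#' @export
build_system_matrix <- function(stacks, grid, psf = NULL, mask_only = TRUE) {
  stacks <- as_stack_list(stacks)
  trips_i <- list(); trips_j <- list(); trips_x <- list()
  row_slice <- list(); row_pixel <- list()
  n_rows <- 0L
  s_id <- 0L
  for (si in seq_along(stacks)) {
    st <- stacks[[si]]
    spsf <- if (is.null(psf)) default_psf(st$thickness, st$inplane) else psf
    for (k in seq_along(st$slices)) {
      s_id <- s_id + 1L
      sk <- st$slices[[k]]
      keep <- if (mask_only) which(as.vector(sk$mask)) else
        seq_len(length(sk$values))
      if (length(keep) == 0L) next
      d <- dim(sk$values)
      pix <- cbind((keep - 1L) %% d[1], (keep - 1L) %/% d[1], 0L)
      P <- apply_transform(sk$transform, voxel_to_world(sk$grid, pix))
      axes <- sk$transform$R %*% sk$grid$direction
      tr <- psf_rows_cpp(to_points(P), axes, spsf$sigma, spsf$truncation,
                         grid$origin, grid$spacing, grid$direction,
                         grid$shape)
      trips_i[[s_id]] <- tr$i + n_rows
      trips_j[[s_id]] <- tr$j
      trips_x[[s_id]] <- tr$x
      row_slice[[s_id]] <- rep.int(s_id, length(keep))
      row_pixel[[s_id]] <- keep
      n_rows <- n_rows + length(keep)
    }
  }
  if (n_rows == 0L) stop("no slice voxels to build a system matrix from")
  i <- unlist(trips_i); j <- unlist(trips_j); x <- unlist(trips_x)
  M <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(n_rows, prod(grid$shape)))
  rs <- Matrix::rowSums(M)
  empty <- rs == 0
  if (all(empty))
    stop("system matrix has no in-grid support: grid does not overlap stacks")
  scl <- numeric(length(rs))
  scl[!empty] <- 1 / rs[!empty]
  M <- methods::as(Matrix::Diagonal(x = scl) %*% M, "CsparseMatrix")
  structure(list(M = M,
                 rows = data.frame(slice = unlist(row_slice),
                                   pixel = unlist(row_pixel)),
                 empty = empty, grid = grid),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("system_matrix: %d slice voxels x %d volume voxels, %d nonzeros, %d empty rows\n",
              nrow(x$M), ncol(x$M), length(x$M@x), sum(x$empty)))
  invisible(x)
}

#' Simulate slice intensities from a volume
#'
#' The linear forward model `y_hat_jk = sum_i m_ijk x_i`.  Rows with no
#' in-grid support return `NA`, never 0.
#'
#' @param volume a [volume3d()] on the grid `M` was built on, or a plain
#'   numeric vector of length `ncol(M$M)`.
#' @param M a [build_system_matrix()] result.
#' @return Numeric vector of simulated intensities, one per system-matrix
#'   row.
#' @export
simulate_slices <- function(volume, M) {
  x <- if (inherits(volume, "volume3d")) {
    if (!all(dim(volume$values) == M$grid$shape))
      stop("volume grid does not match the system matrix grid")
    as.vector(volume$values)
  } else {
    if (length(volume) != ncol(M$M))
      stop("volume vector length does not match the system matrix")
    as.numeric(volume)
  }
  yhat <- as.vector(M$M %*% x)
  yhat[M$empty] <- NA_real_
  yhat
}

#' Dump a system matrix as row,col,value text triplets (debug aid)
#' @param M a [build_system_matrix()] result.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
dump_system_matrix <- function(M, path) {
  tm <- methods::as(M$M, "TsparseMatrix")
  utils::write.table(data.frame(row = tm@i + 1L, col = tm@j + 1L,
                                value = tm@x),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
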