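# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Covers what the package needs: 3-D scalar images, datatypes uint8,
# int16, int32, float32, float64, scl_slope/scl_inter scaling, and the
# voxel-to-world affine from the sform (preferred) or the quaternion
# qform.  Written files use float64 data, sform_code 1 and vox_offset
# 352.  The affine rows are stored as float32 per the format, so world
# coordinates round-trip at single precision.  NIfTI voxel indices are
# zero-based like the package's grids; the direction/spacing/origin
# decomposition assumes (and checks) an orthonormal direction matrix.

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a 3D NIfTI-1 image
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [volume3d()] (no mask) whose grid carries the file's
#'   affine.
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file: short header")
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: sizeof_hdr != 348")
  }
  rd <- function(off, what, n, size)
    readBin(hdr_raw[(off + 1L):(off + n * size)], what, n, size,
            signed = TRUE, endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: bad magic")
  dm <- rd(40L, "integer", 8L, 2L)
  ndim <- dm[1]
  if (ndim < 3L)
    stop("only 3-D NIfTI images are supported")
  if (ndim > 3L && any(dm[seq(5L, ndim + 1L)] > 1L))
    stop("only 3-D NIfTI images are supported")
  shape <- pmax(dm[2:4], 1L)
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  if (sform_code > 0L) {
    A <- rbind(rd(280L, "numeric", 4L, 4L), rd(296L, "numeric", 4L, 4L),
               rd(312L, "numeric", 4L, 4L))
  } else if (qform_code > 0L) {
    q <- rd(256L, "numeric", 3L, 4L)
    off <- rd(268L, "numeric", 3L, 4L)
    b <- q[1]; cq <- q[2]; d <- q[3]
    a2 <- max(0, 1 - b^2 - cq^2 - d^2)
    a <- sqrt(a2)
    R <- rbind(
      c(a^2 + b^2 - cq^2 - d^2, 2 * (b * cq - a * d), 2 * (b * d + a * cq)),
      c(2 * (b * cq + a * d), a^2 + cq^2 - b^2 - d^2, 2 * (cq * d - a * b)),
      c(2 * (b * d - a * cq), 2 * (cq * d + a * b), a^2 + d^2 - b^2 - cq^2))
    qfac <- if (pixdim[1] == -1) -1 else 1
    A <- cbind(R %*% diag(c(pixdim[2:3], qfac * pixdim[4])), off)
  } else {
    A <- cbind(diag(pixdim[2:4]), c(0, 0, 0))
  }
  spacing <- sqrt(colSums(A[, 1:3]^2))
  if (any(spacing <= 0)) stop("invalid NIfTI affine: zero spacing")
  direction <- sweep(A[, 1:3], 2L, spacing, `/`)
  if (!is_orthonormal(direction, tol = 1e-3))
    stop("non-orthogonal NIfTI affine beyond tolerance")
  # re-orthonormalize to numerical precision (affine stored as float32)
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  grid <- image_grid(shape, spacing, origin = A[, 4], direction = direction)

  n <- prod(shape)
  seek(con, where = max(vox_offset, 352), origin = "start")
  vals <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, 1L, signed = FALSE,
                             endian = endian)),
    "4" = as.numeric(readBin(con, "integer", n, 2L, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n, 4L, endian = endian)),
    "16" = readBin(con, "numeric", n, 4L, endian = endian),
    "64" = readBin(con, "numeric", n, 8L, endian = endian),
    stop("unsupported NIfTI datatype: ", datatype))
  if (length(vals) < n) stop("truncated NIfTI data section")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  vals[!is.finite(vals)] <- 0
  volume3d(array(vals, shape), grid)
}

#' Write a 3D image as NIfTI-1
#'
#' @param vol a [volume3d()] (the mask, if any, is not stored).
#' @param path output `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  grid <- vol$grid
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  A <- cbind(grid$direction %*% diag(grid$spacing), grid$origin)

  w_i32(348L)                      # sizeof_hdr
  w_raw(36L)                       # data_type..dim_info (unused)
  w_i16(c(3L, grid$shape, 1L, 1L, 1L, 1L))   # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1-3
  w_i16(0L)                        # intent_code
  w_i16(64L)                       # datatype float64
  w_i16(64L)                       # bitpix
  w_i16(0L)                        # slice_start
  w_f32(c(1, grid$spacing, 0, 0, 0, 0))      # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)             # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_dur, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  desc <- charToRaw("svrsr")
  writeBin(desc, con); w_raw(80L - length(desc))  # descrip[80]
  w_raw(24L)                       # aux_file
  w_i16(0L)                        # qform_code
  w_i16(1L)                        # sform_code
  w_f32(c(0, 0, 0))                # quatern b,c,d
  w_f32(c(0, 0, 0))                # qoffset
  w_f32(A[1, ]); w_f32(A[2, ]); w_f32(A[3, ])
  w_raw(16L)                       # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1L)  # magic
  w_raw(4L)                        # extension flag
  writeBin(as.numeric(vol$values), con, 8L, endian = "little")
  invisible(path)
}
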