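# Stack I/O, transform files and the preprocessing pipeline.

#' Write per-slice diagnostics as TSV
#'
#' One row per slice: id, intensity scale, inlier potential, slice
#' posterior and the hard exclusion flag, as produced by
#' [reconstruct()].
#'
#' @param recon a [reconstruct()] result (or its `diagnostics`
#'   data.frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_slice_report <- function(recon, path) {
  d <- if (is.data.frame(recon)) recon else recon$diagnostics
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export estimated per-slice bias fields as a NIfTI stack
#'
#' Writes one 3D NIfTI per stack whose planes are the estimated
#' log-domain differential bias fields (QC of the intensity matching).
#'
#' @param stacks stacks carrying bias state (e.g. from
#'   [reconstruct()]).
#' @param dir output directory.
#' @return The written paths, invisibly.
#' @export
export_bias_fields <- function(stacks, dir) {
  stacks <- as_stack_list(stacks)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stacks))
  for (si in seq_along(stacks)) {
    st <- stacks[[si]]
    st$slices <- lapply(st$slices, function(sl) {
      sl$values <- sl$bias
      sl
    })
    paths[si] <- file.path(dir, sprintf("bias_stack%02d.nii.gz", si))
    write_stack(st, paths[si])
  }
  invisible(paths)
}

#' Read a stack of slices from a 3D NIfTI file
#'
#' The third voxel axis is the through-plane (slice) axis; each plane
#' becomes one [mri_slice()].  Slice thickness defaults to the
#' through-plane spacing (override for gapped or overlapping
#' acquisitions, where thickness differs from the slice step).
#'
#' @param path NIfTI file.
#' @param thickness slice thickness in mm; `NULL` uses the header's
#'   through-plane spacing.
#' @param orientation free-text label stored on the stack.
#' @return A [slice_stack()].
#' @export
read_stack <- function(path, thickness = NULL, orientation = "") {
  vol <- read_nifti(path)
  volume_to_stack(vol, thickness = thickness, orientation = orientation)
}

#' Split a 3D volume into a stack of slices
#' @param vol a [volume3d()].
#' @inheritParams read_stack
#' @return A [slice_stack()]; the third grid axis becomes the slice axis.
#' @export
volume_to_stack <- function(vol, thickness = NULL, orientation = "") {
  g <- vol$grid
  if (is.null(thickness)) thickness <- g$spacing[3]
  slices <- lapply(seq_len(g$shape[3]), function(k) {
    sg <- image_grid(c(g$shape[1:2], 1L),
                     c(g$spacing[1:2], thickness),
                     origin = g$origin + g$direction[, 3] * g$spacing[3] * (k - 1),
                     direction = g$direction)
    mri_slice(vol$values[, , k], sg, thickness)
  })
  slice_stack(slices, g$spacing[1:2], thickness, orientation = orientation)
}

#' Reassemble a stack into a 3D volume on its native grid
#'
#' Uses the acquired (uncorrected) values and the *nominal* slice
#' geometry (slice motion is ignored): the stack exactly as it would sit
#' in its own NIfTI file, e.g. for stack-to-template registration.
#'
#' @param stack a [slice_stack()].
#' @param corrected use scale/bias-corrected values.
#' @return A [volume3d()] whose mask is the union of slice masks.
#' @export
stack_to_volume <- function(stack, corrected = FALSE) {
  sl1 <- stack$slices[[1]]
  g1 <- sl1$grid
  nz <- length(stack$slices)
  step <- if (nz > 1L)
    sqrt(sum((stack$slices[[2]]$grid$origin - g1$origin)^2)) else
      stack$thickness
  grid <- image_grid(c(g1$shape[1:2], nz), c(g1$spacing[1:2], step),
                     origin = g1$origin, direction = g1$direction)
  vals <- vapply(stack$slices, function(s)
    if (corrected) corrected_values(s) else s$values,
    matrix(0, g1$shape[1], g1$shape[2]))
  msk <- vapply(stack$slices, function(s) s$mask,
                matrix(TRUE, g1$shape[1], g1$shape[2]))
  volume3d(array(vals, grid$shape), grid, mask = array(msk, grid$shape))
}

#' Write a stack as a 3D NIfTI file
#' @param stack a [slice_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  write_nifti(stack_to_volume(stack), path)
}

#' Write per-slice 6-DOF transforms as plain text
#'
#' One row per slice: `rx ry rz tx ty tz` (degrees / mm, the
#' [euler_transform()] convention), whitespace-separated, with a `#`
#' header line.
#'
#' @param transforms list of [rigid_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transforms <- function(transforms, path) {
  m <- t(vapply(transforms, transform_params, numeric(6)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rx_deg ry_deg rz_deg tx_mm ty_mm tz_mm", con)
  utils::write.table(format(m, digits = 17), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-slice transforms written by [write_transforms()]
#' @param path text file.
#' @return List of [rigid_transform()].
#' @export
read_transforms <- function(path) {
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  lapply(seq_len(nrow(m)), function(i)
    euler_transform(m[i, 1], m[i, 2], m[i, 3], m[i, 4], m[i, 5], m[i, 6]))
}

#' Transfer a head mask onto every slice of every stack
#'
#' Samples the (optionally Gaussian-smoothed) mask volume at each
#' slice's current voxel positions and thresholds at 0.5.
#'
#' @param stacks stacks to mask.
#' @param mask_vol a [volume3d()] whose values (or mask) encode the head
#'   region as 0/1.
#' @param smooth_sigma smoothing in mm applied to the mask before
#'   sampling (0 disables).
#' @return The stacks with slice masks replaced.
#' @export
transfer_mask <- function(stacks, mask_vol, smooth_sigma = 2) {
  vals <- if (!is.null(mask_vol$mask)) mask_vol$mask + 0 else
    (mask_vol$values > 0.5) + 0
  if (smooth_sigma > 0)
    vals <- gauss_smooth3d(vals, smooth_sigma / mask_vol$grid$spacing)
  mv <- volume3d(vals, mask_vol$grid)
  map_slices(stacks, function(sl, g) {
    pts <- slice_points(sl, mask_only = FALSE)
    v <- interpolate_volume(mv, pts, outside = 0)
    sl$mask <- matrix(v > 0.5, nrow(sl$values), ncol(sl$values))
    sl
  })
}

crop_slice <- function(sl, rows, cols) {
  idx0 <- c(rows[1] - 1L, cols[1] - 1L, 0L)
  new_origin <- voxel_to_world(sl$grid, idx0)
  g <- image_grid(c(length(rows), length(cols), 1L), sl$grid$spacing,
                  origin = new_origin, direction = sl$grid$direction)
  s2 <- mri_slice(sl$values[rows, cols, drop = FALSE], g, sl$thickness,
                  transform = sl$transform,
                  mask = sl$mask[rows, cols, drop = FALSE])
  s2$scale <- sl$scale
  s2$bias <- sl$bias[rows, cols, drop = FALSE]
  s2
}

#' Preprocess stacks: register to template, mask, crop, normalize
#'
#' The standard preparation before motion correction:
#' \enumerate{
#'   \item the template mask is smoothed and thresholded;
#'   \item every other stack is rigidly registered to the template
#'     stack (multi-start NMI, [register_stack_to_template()]) and its
#'     slices inherit the resulting pose;
#'   \item the mask is transferred to all slices;
#'   \item each stack is cropped in-plane to the mask bounding box with
#'     a margin;
#'   \item each stack is globally rescaled so its masked mean intensity
#'     equals `target_mean` (initializes intensity matching and makes
#'     the edge threshold delta comparable across runs).
#' }
#' Slice order is never changed, so per-slice ground-truth bookkeeping
#' survives preprocessing.
#'
#' @param stacks list of [slice_stack()]; the first is the template
#'   unless `template` says otherwise.
#' @param mask_vol head mask as a [volume3d()] on the template stack
#'   grid (values or mask nonzero inside the head).
#' @param template index of the template stack.
#' @param target_mean masked mean intensity after normalization.
#' @param register_stacks run stack-to-template registration (disable
#'   when stacks are already co-aligned, e.g. simulator output).
#' @param settings a [registration_settings()].
#' @param smooth_sigma mask smoothing in mm.
#' @param pad_px in-plane crop margin in voxels.
#' @return List: `stacks` (preprocessed), `scale_factors` (per stack),
#'   `poses` (per-stack template-alignment transforms), `dropped`
#'   (indices of stacks whose registration failed).
#' @export
preprocess <- function(stacks, mask_vol, template = 1L, target_mean = 100,
                       register_stacks = TRUE,
                       settings = registration_settings(),
                       smooth_sigma = 2, pad_px = 4L) {
  stacks <- as_stack_list(stacks)
  if (!any(mask_vol$values > 0.5) && is.null(mask_vol$mask))
    stop("empty head mask")
  poses <- vector("list", length(stacks))
  dropped <- integer(0)
  if (register_stacks && length(stacks) > 1L) {
    tmpl_vol <- stack_to_volume(stacks[[template]])
    tmpl_vol$mask <- array(interpolate_volume(
      volume3d((if (!is.null(mask_vol$mask)) mask_vol$mask else
        mask_vol$values > 0.5) + 0, mask_vol$grid),
      grid_points(tmpl_vol$grid), outside = 0) > 0.5,
      tmpl_vol$grid$shape)
    for (si in seq_along(stacks)) {
      if (si == template) { poses[[si]] <- rigid_transform(); next }
      fit <- tryCatch(
        register_stack_to_template(stack_to_volume(stacks[[si]]),
                                   tmpl_vol, settings),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("stack ", si, " dropped: registration to template failed")
        dropped <- c(dropped, si)
        next
      }
      # template-space point p matches stack point T(p): bring the stack
      # over by T^-1
      pose <- invert(fit$transform)
      poses[[si]] <- pose
      stacks[[si]]$pose <- pose
      stacks[[si]]$slices <- lapply(stacks[[si]]$slices, function(sl) {
        sl$transform <- compose(pose, sl$transform)
        sl
      })
    }
    if (length(dropped)) stacks <- stacks[-dropped]
  } else {
    poses <- rep(list(rigid_transform()), length(stacks))
  }

  stacks <- transfer_mask(stacks, mask_vol, smooth_sigma)

  # in-plane crop to the union mask bounding box per stack
  stacks <- lapply(stacks, function(st) {
    msk <- Reduce(`|`, lapply(st$slices, `[[`, "mask"))
    if (!any(msk)) return(st)
    rw <- range(which(rowSums(msk) > 0))
    cl <- range(which(colSums(msk) > 0))
    rows <- max(1L, rw[1] - pad_px):min(nrow(msk), rw[2] + pad_px)
    cols <- max(1L, cl[1] - pad_px):min(ncol(msk), cl[2] + pad_px)
    st$slices <- lapply(st$slices, crop_slice, rows = rows, cols = cols)
    st
  })

  # per-stack intensity normalization to the target masked mean
  scale_factors <- vapply(stacks, function(st) {
    v <- unlist(lapply(st$slices, function(s) s$values[s$mask]))
    if (!length(v) || mean(v) <= 0) 1 else target_mean / mean(v)
  }, numeric(1))
  for (si in seq_along(stacks))
    stacks[[si]]$slices <- lapply(stacks[[si]]$slices, function(sl) {
      sl$values <- sl$values * scale_factors[si]
      sl
    })
  list(stacks = stacks, scale_factors = scale_factors, poses = poses,
       dropped = dropped)
}
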