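#' Acquisition-simulation settings
#'
#' Describes the synthetic acquisition protocol: oriented stacks of thick
#' slices sampled through a known volume via the PSF, per-slice rigid
#' motion, per-slice intensity corruption (scales in `scale_range`, smooth
#' multiplicative bias fields smoothed with a `bias_sigma` = 12 mm
#' Gaussian), additive Gaussian noise with sigma = `noise_fraction` x mean
#' intensity (0.025 by default), plus deliberately displaced slices
#' (beyond the registration capture range) and motion-corrupted slices
#' (in-plane segment-shift ghosting).
#'
#' Defaults reproduce the reference simulation design: three orthogonal
#' stacks, slice thickness 3 mm, in-plane 1 mm, no gap, 6 displaced and 5
#' corrupted slices per three stacks, with per-slice motion bounded by 3
#' degrees / 2 mm (smooth across the slice ordering) which yields mean
#' voxel displacements in the 1.3-2.4 mm range.
#'
#' @param n_stacks number of stacks (orientations cycle through axial,
#'   coronal, sagittal).
#' @param slices_per_stack slices per stack; `NULL` (default) covers the
#'   volume extent along each stack normal.
#' @param thickness slice thickness in mm.
#' @param inplane in-plane spacing in mm.
#' @param gap slice gap in mm (negative values overlap).
#' @param noise_fraction noise sigma as a fraction of the mean in-mask
#'   intensity of the ground-truth volume.
#' @param bias_sigma smoothness (mm) of the simulated bias fields.
#' @param bias_amplitude target mean |log-bias| over head voxels
#'   (0 disables bias).
#' @param scale_range range the true per-slice scales are drawn from
#'   (`c(1, 1)` disables scaling).
#' @param n_displaced,n_corrupted number of grossly displaced /
#'   artifact-corrupted slices over all stacks; `NULL` gives 2 and 5/3
#'   per stack respectively.
#' @param max_rotation,max_translation bounds of the smooth per-slice
#'   motion (degrees / mm); 0 disables motion.
#' @param displacement_translation,displacement_rotation magnitude of the
#'   outlier displacements (mm / degrees), chosen beyond the registration
#'   capture range.
#' @param seed integer seed fixing the full draw.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_stacks = 3L, slices_per_stack = NULL,
                            thickness = 3, inplane = 1, gap = 0,
                            noise_fraction = 0.025,
                            bias_sigma = 12, bias_amplitude = 0.06,
                            scale_range = c(0.8, 1.2),
                            n_displaced = NULL, n_corrupted = NULL,
                            max_rotation = 3, max_translation = 2,
                            displacement_translation = 15,
                            displacement_rotation = 30,
                            seed = 1L) {
  if (is.null(n_displaced)) n_displaced <- 2L * n_stacks
  if (is.null(n_corrupted)) n_corrupted <- round(5 * n_stacks / 3)
  stopifnot(n_stacks >= 1L, thickness > 0, inplane > 0,
            noise_fraction >= 0, bias_sigma > 0, bias_amplitude >= 0,
            length(scale_range) == 2L, scale_range[1] <= scale_range[2],
            n_displaced >= 0, n_corrupted >= 0,
            max_rotation >= 0, max_translation >= 0)
  structure(list(n_stacks = as.integer(n_stacks),
                 slices_per_stack = slices_per_stack,
                 thickness = thickness, inplane = inplane, gap = gap,
                 noise_fraction = noise_fraction, bias_sigma = bias_sigma,
                 bias_amplitude = bias_amplitude, scale_range = scale_range,
                 n_displaced = as.integer(n_displaced),
                 n_corrupted = as.integer(n_corrupted),
                 max_rotation = max_rotation,
                 max_translation = max_translation,
                 displacement_translation = displacement_translation,
                 displacement_rotation = displacement_rotation,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Brain-like nested-ellipsoid phantom
#'
#' Deterministic (given `seed`) piecewise-smooth phantom standing in for
#' a neonatal brain volume: a bright skull rim, a CSF layer, a cortical
#' ribbon, white matter, off-center ventricles and an asymmetric deep
#' gray nucleus (so rigid orientation is identifiable), plus mild smooth
#' intensity texture.  Intensities lie in \[0, 100\]; the mask marks the
#' head (inside the skull rim).
#'
#' @param size_mm physical extent per axis in mm (scalar or length 3).
#' @param spacing_mm isotropic voxel size in mm.
#' @param seed integer seed for the texture field.
#' @return A [volume3d()] with mask, centered at world origin.
#' @export
make_phantom <- function(size_mm = 64, spacing_mm = 1, seed = 1L) {
  if (any(size_mm <= 0) || spacing_mm <= 0)
    stop("sizes must be positive")
  size_mm <- rep(size_mm, length.out = 3L)
  shape <- pmax(8L, as.integer(round(size_mm / spacing_mm)))
  grid <- image_grid(shape, rep(spacing_mm, 3L),
                     origin = -(shape - 1) / 2 * spacing_mm)
  p <- grid_points(grid)
  # normalized radial coordinates of the head ellipsoid
  semi <- size_mm / 2 * c(0.88, 0.92, 0.84)
  q <- sweep(p, 2L, semi, `/`)
  r <- sqrt(rowSums(q^2))
  val <- numeric(nrow(p))
  val[r < 1.00] <- 92            # skull rim
  val[r < 0.94] <- 30            # CSF layer
  val[r < 0.86] <- 62            # cortical gray matter ribbon
  val[r < 0.72] <- 45            # white matter
  # ventricles: two off-center ellipsoids, and one asymmetric deep nucleus
  vshift <- c(0.16, 0, 0.05) * semi
  for (sgn in c(-1, 1)) {
    ctr <- sgn * vshift
    qv <- sweep(p, 2L, ctr, `-`)
    qv <- sweep(qv, 2L, semi * c(0.12, 0.28, 0.14), `/`)
    val[sqrt(rowSums(qv^2)) < 1] <- 24
  }
  qn <- sweep(p, 2L, semi * c(0.30, 0.25, -0.18), `-`)
  qn <- sweep(qn, 2L, semi * c(0.16, 0.14, 0.12), `/`)
  val[sqrt(rowSums(qn^2)) < 1] <- 72
  arr <- array(val, shape)
  # mild smooth texture inside the head
  old_seed <- set_local_seed(seed)
  on.exit(restore_seed(old_seed))
  tex <- gauss_smooth3d(array(stats::rnorm(prod(shape)), shape),
                        3 / spacing_mm)
  tex <- tex / stats::sd(tex) * 1.5
  head <- array(r < 1.00, shape)
  arr[head] <- arr[head] + tex[head]
  # soften tissue boundaries (partial-volume analog)
  arr <- gauss_smooth3d(arr, 0.6 / spacing_mm)
  arr[arr < 0] <- 0
  volume3d(arr, grid, mask = head)
}

set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Stack geometry covering `grid`: slice axes from `rotation` (columns 1-2
# in-plane, column 3 normal), in-plane FOV covering the grid with margin.
stack_geometry <- function(grid, rotation, thickness, inplane, gap = 0,
                           n_slices = NULL, margin = 4) {
  corners <- voxel_to_world(grid, as.matrix(expand.grid(
    c(0, grid$shape[1] - 1), c(0, grid$shape[2] - 1),
    c(0, grid$shape[3] - 1))))
  center <- colMeans(corners)
  proj <- sweep(corners, 2L, center) %*% rotation
  ext <- apply(abs(proj), 2L, max) + margin
  n1 <- ceiling(2 * ext[1] / inplane) + 1L
  n2 <- ceiling(2 * ext[2] / inplane) + 1L
  step <- thickness + gap
  if (is.null(n_slices)) n_slices <- ceiling(2 * ext[3] / step) + 1L
  z0 <- -(n_slices - 1) / 2 * step
  slice_origin <- function(k)
    center - rotation[, 1] * (n1 - 1) / 2 * inplane -
      rotation[, 2] * (n2 - 1) / 2 * inplane +
      rotation[, 3] * (z0 + (k - 1) * step)
  list(n1 = n1, n2 = n2, n_slices = as.integer(n_slices), center = center,
       rotation = rotation, step = step,
       grids = lapply(seq_len(n_slices), function(k)
         image_grid(c(n1, n2, 1L), c(inplane, inplane, thickness),
                    origin = slice_origin(k), direction = rotation)))
}

stack_orientations <- function(n) {
  base <- list(diag(3),                       # axial
               euler_matrix(90, 0, 0),        # coronal
               euler_matrix(0, 90, 0))        # sagittal
  lapply(seq_len(n) - 1L, function(i) base[[i %% 3L + 1L]])
}

# rigid motion about a fixed center: p -> R (p - ctr) + ctr + t
centered_transform <- function(rx, ry, rz, t, center) {
  R <- euler_matrix(rx, ry, rz)
  rigid_transform(R, as.numeric(center - R %*% center) + t)
}

#' Simulate a motion-corrupted multi-stack acquisition
#'
#' Runs the full corruption protocol on a known volume: smooth per-slice
#' rigid motion, PSF sampling through the true transforms, per-slice
#' scales and smoothed bias fields, additive Gaussian noise, displaced
#' outlier slices and ghosting-corrupted slices.  All truths are
#' recorded.  Sub-seeds for motion, intensity, noise and outlier draws
#' are derived independently from `spec$seed`, so e.g. disabling the
#' intensity corruption does not change the motion draw.
#'
#' The observation model per slice k is
#' `y = exp(b) * (M x) / s + noise`, i.e. the model quantities `s_k`
#' (scale) and `b_jk` (log bias) recorded as truth are exactly what the
#' reconstruction's intensity matching estimates.
#'
#' @param volume ground-truth [volume3d()].
#' @param spec a [simulation_spec()].
#' @return A list with `stacks` (list of [slice_stack()], slice
#'   transforms set to identity, i.e. the unknown-motion starting point)
#'   and `truth` (ground-truth record: `volume`, per-slice `transforms`,
#'   `scales`, `biases`, `labels` in clean/displaced/corrupted,
#'   `mean_displacement_mm`, and the per-slice noise-free clean
#'   intensities `clean_values` used by the reference method variant).
#' @export
simulate_acquisition <- function(volume, spec) {
  stopifnot(inherits(volume, "volume3d"), inherits(spec, "simulation_spec"))
  old_seed <- set_local_seed(spec$seed)
  on.exit(restore_seed(old_seed))
  sub <- sample.int(.Machine$integer.max - 1L, 5L)

  orientations <- stack_orientations(spec$n_stacks)
  geoms <- lapply(orientations, function(Rk)
    stack_geometry(volume$grid, Rk, spec$thickness, spec$inplane,
                   spec$gap, spec$slices_per_stack))
  n_per <- vapply(geoms, `[[`, integer(1), "n_slices")
  n_slices <- sum(n_per)
  if (spec$n_displaced + spec$n_corrupted > n_slices)
    stop("more outlier slices requested than slices simulated")

  # ---- motion -------------------------------------------------------
  set.seed(sub[1])
  center <- geoms[[1]]$center
  transforms <- vector("list", n_slices)
  gid <- 0L
  for (si in seq_along(geoms)) {
    nz <- n_per[si]
    par6 <- vapply(1:6, function(j) {
      s <- smooth_series(stats::rnorm(nz), 5L)
      if (max(abs(s)) < 1e-12) return(rep(0, nz))
      amp <- stats::runif(1, 0.3, 1) *
        if (j <= 3) spec$max_rotation else spec$max_translation
      s / max(abs(s)) * amp
    }, numeric(nz))
    par6 <- matrix(par6, nrow = nz)
    for (k in seq_len(nz)) {
      gid <- gid + 1L
      transforms[[gid]] <- centered_transform(
        par6[k, 1], par6[k, 2], par6[k, 3], par6[k, 4:6], center)
    }
  }

  # ---- outlier selection -------------------------------------------
  # outliers are drawn among slices that substantially intersect the
  # head (>= 25% of the maximum in-head voxel count): corrupting a
  # near-empty edge slice produces no identifiable artifact, whereas the
  # reference evaluation corrupts visibly brain-containing slices
  set.seed(sub[2])
  mask_arr <- volume_mask(volume) + 0
  mask_vol <- volume3d(mask_arr, volume$grid)
  head_count <- numeric(n_slices)
  gid_e <- 0L
  for (si in seq_along(geoms)) {
    geo <- geoms[[si]]
    for (k in seq_len(geo$n_slices)) {
      gid_e <- gid_e + 1L
      idx <- as.matrix(expand.grid(seq_len(geo$n1) - 1L,
                                   seq_len(geo$n2) - 1L))
      pts <- voxel_to_world(geo$grids[[k]], cbind(idx, 0L))
      head_count[gid_e] <- sum(interpolate_volume(mask_vol, pts,
                                                  outside = 0) > 0.5)
    }
  }
  eligible <- which(head_count >= 0.25 * max(head_count))
  n_out <- spec$n_displaced + spec$n_corrupted
  if (n_out > length(eligible))
    stop("more outlier slices requested than eligible (head-crossing) slices")
  out_idx <- sample(eligible, n_out)
  displaced <- utils::head(out_idx, spec$n_displaced)
  corrupted <- utils::tail(out_idx, spec$n_corrupted)
  labels <- rep("clean", n_slices)
  labels[displaced] <- "displaced"
  labels[corrupted] <- "corrupted"
  for (g in displaced) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- spec$displacement_rotation * sample(c(-1, 1), 1)
    tr <- stats::rnorm(3); tr <- tr / sqrt(sum(tr^2)) *
      spec$displacement_translation
    disp <- centered_transform(ax[1] * ang, ax[2] * ang, ax[3] * ang,
                               tr, center)
    transforms[[g]] <- compose(disp, transforms[[g]])
  }

  # ---- intensity corruption draws ----------------------------------
  set.seed(sub[3])
  scales <- stats::runif(n_slices, spec$scale_range[1], spec$scale_range[2])
  bias_fields <- vector("list", n_slices)

  mu <- mean(volume$values[volume_mask(volume)])
  set.seed(sub[4])
  noise_seeds <- sample.int(.Machine$integer.max - 1L, n_slices)
  set.seed(sub[5])
  bias_seeds <- sample.int(.Machine$integer.max - 1L, n_slices)

  # ---- simulate stacks ---------------------------------------------
  stacks <- vector("list", spec$n_stacks)
  clean_values <- vector("list", n_slices)
  disp_sum <- 0; disp_n <- 0
  gid <- 0L
  for (si in seq_along(geoms)) {
    geo <- geoms[[si]]
    gid0 <- gid
    true_slices <- lapply(seq_len(geo$n_slices), function(k)
      mri_slice(matrix(0, geo$n1, geo$n2), geo$grids[[k]], spec$thickness,
                transform = transforms[[gid0 + k]]))
    Mst <- build_system_matrix(
      slice_stack(true_slices, spec$inplane, spec$thickness),
      volume$grid, mask_only = FALSE)
    yall <- simulate_slices(volume, Mst)
    yall[is.na(yall)] <- 0
    slices <- vector("list", geo$n_slices)
    for (k in seq_len(geo$n_slices)) {
      gid <- gid + 1L
      sk <- true_slices[[k]]
      yclean <- matrix(0, geo$n1, geo$n2)
      sel <- Mst$rows$slice == k
      yclean[Mst$rows$pixel[sel]] <- yall[sel]
      clean_values[[gid]] <- yclean
      support <- yclean > 0.05 * mu

      # bias field: smoothed white noise, zero-mean over head support,
      # scaled to the target mean |b|
      b <- matrix(0, geo$n1, geo$n2)
      if (spec$bias_amplitude > 0 && any(support)) {
        set.seed(bias_seeds[gid])
        b <- gauss_smooth2d(matrix(stats::rnorm(geo$n1 * geo$n2),
                                   geo$n1, geo$n2),
                            spec$bias_sigma / spec$inplane)
        b <- b - mean(b[support])
        mb <- mean(abs(b[support]))
        if (mb > 0) b <- b * (spec$bias_amplitude / mb)
      }
      bias_fields[[gid]] <- b
      s_true <- scales[gid]
      y <- exp(b) * yclean / s_true

      if (labels[gid] == "corrupted")
        y <- ghost_corrupt(y, seed = bias_seeds[gid])

      if (spec$noise_fraction > 0) {
        set.seed(noise_seeds[gid])
        y <- y + stats::rnorm(length(y), 0, spec$noise_fraction * mu)
      }
      sk$values <- y
      sk$transform <- rigid_transform()  # motion is unknown downstream
      slices[[k]] <- sk

      # Table-1 style motion magnitude: mean displacement of head voxels
      if (labels[gid] == "clean" && any(support)) {
        pix <- which(support)
        d <- dim(yclean)
        idx <- cbind((pix - 1L) %% d[1], (pix - 1L) %/% d[1], 0L)
        base <- voxel_to_world(geo$grids[[k]], idx)
        moved <- apply_transform(transforms[[gid]], base)
        disp_sum <- disp_sum + sum(sqrt(rowSums((moved - base)^2)))
        disp_n <- disp_n + length(pix)
      }
    }
    stacks[[si]] <- slice_stack(slices, spec$inplane, spec$thickness,
                                orientation = c("axial", "coronal",
                                                "sagittal")[(si - 1L) %% 3L + 1L])
  }

  truth <- list(volume = volume, transforms = transforms, scales = scales,
                biases = bias_fields, labels = labels,
                clean_values = clean_values,
                mean_displacement_mm = if (disp_n) disp_sum / disp_n else 0,
                spec = spec)
  list(stacks = stacks, truth = truth)
}

# In-plane segment-shift ghosting artifact: a central band of the slice
# is replaced by a blend of itself and a copy shifted along the first
# in-plane axis by 25-40% of the field of view (documented stand-in for
# sudden-motion k-space ghosting).
ghost_corrupt <- function(y, seed) {
  old_seed <- set_local_seed(seed + 7L)
  on.exit(restore_seed(old_seed))
  n <- nrow(y)
  shift <- round(stats::runif(1, 0.25, 0.4) * n)
  band <- seq(round(n * 0.25), round(n * 0.75))
  src <- ((band - 1 + shift) %% n) + 1
  y[band, ] <- 0.45 * y[band, ] + 0.55 * y[src, ]
  y
}

#' Hand ground-truth transforms (and optionally masks) to stacks
#'
#' Utility for known-alignment experiments: copies the true per-slice
#' transforms from a [simulate_acquisition()] truth record onto the
#' stacks.
#'
#' @param stacks stacks from [simulate_acquisition()].
#' @param truth matching truth record.
#' @return The stacks with slice transforms set to the truth.
#' @export
apply_true_transforms <- function(stacks, truth) {
  map_slices(stacks, function(sl, g) {
    sl$transform <- truth$transforms[[g]]
    sl
  })
}
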