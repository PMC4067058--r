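#' Normalized root-mean-square error between two volumes
#'
#' RMS intensity error over the evaluation region divided by the mean
#' intensity of the reference: `sqrt(mean((x' - x*)^2)) / mean(x*)`.
#'
#' @param recon evaluated volume (array or [volume3d()], same grid as
#'   the reference).
#' @param reference reference volume.
#' @param mask logical evaluation region; defaults to the reference
#'   mask (all voxels when absent).
#' @return Scalar NRMSE.
#' @export
nrmse <- function(recon, reference, mask = NULL) {
  v <- metric_pair(recon, reference, mask)
  if (abs(mean(v$ref)) <= 0) stop("reference mean is zero over the mask")
  sqrt(mean((v$rec - v$ref)^2)) / mean(v$ref)
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 log10(MAX / RMSE)` with `MAX` the maximum of the reference
#' volume; identical volumes give `Inf` explicitly.
#'
#' @inheritParams nrmse
#' @return Scalar PSNR in dB (`Inf` for a zero RMSE).
#' @export
psnr <- function(recon, reference, mask = NULL) {
  v <- metric_pair(recon, reference, mask)
  rmse <- sqrt(mean((v$rec - v$ref)^2))
  mx <- max(if (inherits(reference, "volume3d")) reference$values else reference)
  if (rmse == 0) return(Inf)
  20 * log10(mx / rmse)
}

metric_pair <- function(recon, reference, mask) {
  rec <- if (inherits(recon, "volume3d")) recon$values else as.array(recon)
  ref <- if (inherits(reference, "volume3d")) reference$values else
    as.array(reference)
  if (!all(dim(rec) == dim(ref)))
    stop("volumes must share a grid for intensity metrics")
  if (is.null(mask))
    mask <- if (inherits(reference, "volume3d") && !is.null(reference$mask))
      reference$mask else array(TRUE, dim(ref))
  list(rec = rec[mask], ref = ref[mask])
}

#' Target registration error between two transform sets
#'
#' Mean Euclidean distance `|T'(u) - T*(u)|` over the in-ROI voxels of
#' the included slices.  Excluded from the mean (mirroring the
#' evaluation protocol) are slices labeled corrupted, slices labeled
#' displaced (assigned a displacement beyond the registration capture
#' range), and slices with fewer than `min_roi` in-ROI voxels.
#'
#' @param est list of estimated [rigid_transform()]s, one per slice.
#' @param truth list of true [rigid_transform()]s, same length.
#' @param points list of n_k x 3 matrices of slice voxel world positions
#'   (the in-ROI voxels of each slice).
#' @param labels character per slice: `"clean"`, `"displaced"`,
#'   `"corrupted"` (only clean slices are included).
#' @param min_roi minimum in-ROI voxel count for inclusion.
#' @return List: `mean_mm` over included slices' voxels, `per_slice`
#'   (NA for excluded slices), `included` logical vector.
#' @export
tre <- function(est, truth, points, labels = rep("clean", length(est)),
                min_roi = 50L) {
  stopifnot(length(est) == length(truth), length(est) == length(points))
  n <- length(est)
  per <- rep(NA_real_, n)
  counts <- integer(n)
  included <- labels == "clean" &
    vapply(points, nrow, integer(1)) >= min_roi
  tot <- 0; m <- 0L
  for (k in seq_len(n)) {
    if (nrow(points[[k]]) == 0L) next
    d <- sqrt(rowSums((apply_transform(est[[k]], points[[k]]) -
                         apply_transform(truth[[k]], points[[k]]))^2))
    per[k] <- mean(d)
    counts[k] <- length(d)
    if (included[k]) { tot <- tot + sum(d); m <- m + length(d) }
  }
  if (m == 0L) stop("no included slices for TRE")
  list(mean_mm = tot / m, per_slice = per, included = included)
}

#' Align and intensity-match a reconstruction to a reference volume
#'
#' The pre-metric step of the simulated evaluation: rigidly register
#' the reconstruction to the reference (NMI), resample it on the
#' reference grid, and remove the global scale and smooth differential
#' bias field between the two using the package's own intensity
#' matching (the pair is treated as a single slice/simulation pair per
#' axial plane).  Because only differential bias is ever estimated, the
#' reconstruction can be arbitrarily smoothly biased relative to the
#' reference without penalty.
#'
#' @param recon reconstructed [volume3d()].
#' @param reference reference [volume3d()] (with mask).
#' @param settings a [registration_settings()].
#' @param register run the rigid alignment (set FALSE when both volumes
#'   already live on the same grid and pose).
#' @param bias a [bias_settings()] for the differential-bias removal.
#' @return A [volume3d()] on the reference grid, intensity-matched.
#' @export
match_to_reference <- function(recon, reference,
                               settings = registration_settings(),
                               register = TRUE,
                               bias = bias_settings()) {
  if (register) {
    fit <- register_stack_to_template(recon, reference, settings)
    tf <- fit$transform
  } else tf <- rigid_transform()
  pts <- grid_points(reference$grid)
  vals <- interpolate_volume(recon, apply_transform(tf, pts))
  arr <- array(vals, reference$grid$shape)
  mask <- volume_mask(reference) & !is.na(arr)
  arr[is.na(arr)] <- 0
  # global scale (least-squares gain on in-mask voxels)
  num <- sum(arr[mask] * reference$values[mask])
  den <- sum(arr[mask]^2)
  s <- if (den > 0) num / den else 1
  arr <- arr * s
  # differential bias via the slice machinery, plane by plane
  sb <- bias_settings(bias$sigma, bias$enabled)
  for (z in seq_len(dim(arr)[3])) {
    mz <- mask[, , z]
    if (sum(mz) < 10) next
    g2 <- image_grid(c(dim(arr)[1:2], 1L), reference$grid$spacing)
    sl <- mri_slice(arr[, , z], g2, reference$grid$spacing[3], mask = mz)
    for (i in 1:3)
      sl <- update_bias(sl, reference$values[, , z],
                        matrix(1, dim(arr)[1], dim(arr)[2]), sb)
    # accumulated bias is recon-relative-to-reference; remove it
    arr[, , z] <- exp(-sl$bias) * arr[, , z]
  }
  volume3d(arr, reference$grid, mask = reference$mask)
}

#' Leave-one-out evaluation of a reconstruction
#'
#' Holds out one stack, takes a volume reconstructed from the others,
#' aligns the held-out slices to it, and alternates slice-to-volume
#' registration with intensity matching until the sum of squared
#' differences between the held-out and simulated slices stops
#' improving (relative tolerance `tol`, at most `max_alt` alternations).
#' Returns the NRMSE over the held-out slice voxels normalized by the
#' mean in-mask intensity of the reconstructed volume.
#'
#' @param volume reconstructed [volume3d()] (from the retained stacks).
#' @param held_out a [slice_stack()] excluded from that reconstruction.
#' @param settings a [registration_settings()].
#' @param bias a [bias_settings()].
#' @param tol relative SSD improvement below which the alternation
#'   stops.
#' @param max_alt alternation cap.
#' @param register run the initial/iterated slice registrations (set
#'   FALSE when alignment is known).
#' @return List: `nrmse`, `ssd_trace`, `stack` (held-out stack with
#'   final transforms and intensity state).
#' @export
leave_one_out <- function(volume, held_out,
                          settings = registration_settings(),
                          bias = bias_settings(), tol = 1e-4,
                          max_alt = 10L, register = TRUE) {
  st <- held_out
  ssd_trace <- numeric(0)
  prev <- Inf
  for (alt in seq_len(max_alt)) {
    if (register)
      st <- map_slices(st, function(sl, g) {
        fit <- register_slice_to_volume(sl, volume, settings)
        sl$transform <- fit$transform
        sl
      })[[1]]
    M <- build_system_matrix(st, volume$grid)
    yhat <- simulate_slices(volume, M)
    rows <- M$rows
    slices <- all_slices(st)
    y <- extract_rows(slices, rows, "values")
    bflat <- extract_rows(slices, rows, "bias")
    scales <- vapply(slices, `[[`, numeric(1), "scale")
    n_slices <- length(slices)
    up <- update_scales(y, yhat, rep(1, length(y)), bflat, rows$slice,
                        n_slices, scales)
    scales <- up$scales
    for (s_id in seq_len(n_slices)) {
      sel <- rows$slice == s_id
      if (!any(sel)) next
      sl <- slices[[s_id]]
      sl$scale <- scales[s_id]
      sim <- matrix(NA_real_, nrow(sl$values), ncol(sl$values))
      sim[rows$pixel[sel]] <- yhat[sel]
      sl <- update_bias(sl, sim, matrix(1, nrow(sl$values), ncol(sl$values)),
                        bias)
      slices[[s_id]] <- sl
    }
    st <- map_slices(st, function(sl, g) slices[[g]])[[1]]
    bflat <- extract_rows(slices, rows, "bias")
    ystar <- scales[rows$slice] * exp(-bflat) * y
    ok <- !is.na(yhat)
    ssd <- sum((ystar - yhat)[ok]^2)
    ssd_trace <- c(ssd_trace, ssd)
    if (is.finite(prev) && (prev - ssd) / max(prev, .Machine$double.eps) < tol)
      break
    prev <- ssd
  }
  mu <- mean(volume$values[volume_mask(volume)])
  list(nrmse = sqrt(mean((ystar - yhat)[ok]^2)) / mu,
       ssd_trace = ssd_trace, stack = st)
}
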