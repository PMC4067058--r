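#' Registration settings
#'
#' @param bins joint-histogram bins for NMI (>= 8).
#' @param min_overlap minimum overlap fraction (of the fixed samples)
#'   for a candidate alignment to be considered.
#' @param step_mm,step_deg initial pattern-search step sizes.
#' @param tol_mm,tol_deg step sizes at which the search stops.
#' @param max_evals cap on cost evaluations per registration.
#' @param min_mask_voxels slices with fewer in-mask voxels are skipped
#'   and flagged (too little information to register).
#' @param motion_iterations interleaved motion-correction iterations
#'   (typical range 6-16; more for subjects with more motion).
#' @param parzen_sigma Gaussian smoothing of the joint histogram (in
#'   bins) used inside the registration cost; 0 disables.  Smoothing
#'   removes binning noise from the NMI landscape without changing its
#'   optima materially.
#' @param psf_taps through-plane sample points for slice registration:
#'   the volume is averaged at `psf_taps` Gaussian-weighted offsets
#'   along the slice normal (spacing one through-plane sigma), so the
#'   samples mimic the thick-slice acquisition instead of a
#'   zero-thickness plane.  1 (the default) disables: the averaged
#'   samples help one-shot registration to a converged volume but slow
#'   the interleaved loop's convergence in practice.
#' @return An object of class `registration_settings`.
#' @export
registration_settings <- function(bins = 32L, min_overlap = 0.5,
                                  step_mm = 1, step_deg = 1,
                                  tol_mm = 0.1, tol_deg = 0.1,
                                  max_evals = 600L, min_mask_voxels = 50L,
                                  motion_iterations = 9L,
                                  parzen_sigma = 1, psf_taps = 1L) {
  stopifnot(bins >= 8L, motion_iterations >= 1L, step_mm > 0, step_deg > 0,
            psf_taps >= 1L, psf_taps %% 2L == 1L)
  structure(list(bins = as.integer(bins), min_overlap = min_overlap,
                 step_mm = step_mm, step_deg = step_deg,
                 tol_mm = tol_mm, tol_deg = tol_deg,
                 max_evals = as.integer(max_evals),
                 min_mask_voxels = as.integer(min_mask_voxels),
                 motion_iterations = as.integer(motion_iterations),
                 parzen_sigma = parzen_sigma,
                 psf_taps = as.integer(psf_taps)),
            class = "registration_settings")
}

# NMI with an optionally Parzen-smoothed joint histogram (the exported
# nmi() keeps the raw-histogram definition; this is the optimizer cost).
nmi_cost <- function(a, b, bins, parzen_sigma = 0) {
  if (parzen_sigma <= 0) return(nmi(a, b, bins))
  ia <- bin_index(a, bins)
  ib <- bin_index(b, bins)
  J <- matrix(tabulate(ia + bins * (ib - 1L), bins * bins), bins, bins)
  K <- gauss_band_matrix(bins, parzen_sigma)
  J <- K %*% J %*% t(K)
  pj <- J / sum(J)
  pa <- rowSums(pj); pb <- colSums(pj)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hab <- H(pj)
  if (hab <= 0) return(2)
  (H(pa) + H(pb)) / hab
}

#' Normalized mutual information of two sampled images
#'
#' Studholme's overlap-invariant form `NMI = (H(A) + H(B)) / H(A, B)`
#' from a joint histogram of the paired samples; lies in \[1, 2\] and is
#' invariant to positive affine intensity mappings (up to binning),
#' which is what makes it robust to the scale and low-magnitude bias
#' inconsistencies of the slices.
#'
#' @param a,b paired intensity samples (equal length; pairs with any
#'   `NA` are dropped).
#' @param bins histogram bins per axis.
#' @return Scalar NMI.
#' @export
nmi <- function(a, b, bins = 64L) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no overlapping samples for NMI")
  ia <- bin_index(a, bins)
  ib <- bin_index(b, bins)
  joint <- tabulate(ia + bins * (ib - 1L), bins * bins)
  pj <- joint[joint > 0] / length(a)
  hab <- -sum(pj * log(pj))
  pa <- tabulate(ia, bins) / length(a)
  pb <- tabulate(ib, bins) / length(a)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (hab <= 0) return(2)  # both images constant on the overlap
  (ha + hb) / hab
}

bin_index <- function(x, bins) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(rep(1L, length(x)))
  i <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(i, bins)
}

# Pattern (coordinate) search over the 6 rigid parameters
# (rx, ry, rz in degrees, tx, ty, tz in mm) maximizing `cost(par)`.
pattern_search <- function(cost, par0, settings) {
  steps <- c(rep(settings$step_deg, 3), rep(settings$step_mm, 3))
  tols <- c(rep(settings$tol_deg, 3), rep(settings$tol_mm, 3))
  best <- cost(par0)
  par <- par0
  evals <- 1L
  # steepest ascent: evaluate all 12 axis moves, take the best; halve the
  # steps when no move improves (first-improvement walks are noticeably
  # less reliable on histogram-based costs)
  while (any(steps > tols) && evals < settings$max_evals) {
    cand <- vector("list", 12L)
    for (j in 1:6) for (s in 1:2) {
      p2 <- par
      p2[j] <- p2[j] + c(1, -1)[s] * steps[j]
      cand[[(j - 1L) * 2L + s]] <- p2
    }
    vals <- vapply(cand, cost, numeric(1))
    evals <- evals + 12L
    if (max(vals) > best + 1e-12) {
      best <- max(vals)
      par <- cand[[which.max(vals)]]
    } else steps <- steps / 2
  }
  list(par = par, value = best, evals = evals)
}

# rigid perturbation about a center point, composed AFTER `base`
perturbed_transform <- function(par, center, base) {
  compose(centered_transform(par[1], par[2], par[3], par[4:6], center),
          base)
}

#' Register a single slice to a volume
#'
#' 6-DOF local maximization of NMI between the slice's in-mask
#' intensities and the volume interpolated at the transformed slice
#' voxel positions, started from the slice's current transform.  Slices
#' with too few in-mask voxels or (near-)constant intensity are flagged
#' and keep their transform.
#'
#' @param slice an [mri_slice()].
#' @param volume a [volume3d()].
#' @param settings a [registration_settings()].
#' @return List: `transform` (updated [rigid_transform()]), `nmi`,
#'   `flagged` (TRUE when the slice could not be registered).
#' @export
register_slice_to_volume <- function(slice, volume,
                                     settings = registration_settings()) {
  n_in <- sum(slice$mask)
  vals <- slice$values[slice$mask]
  if (n_in < settings$min_mask_voxels ||
      max(vals) - min(vals) < 1e-9 * max(abs(vals), 1))
    return(list(transform = slice$transform, nmi = NA_real_,
                flagged = TRUE))
  base_pts <- slice_points(slice, mask_only = TRUE,
                           transform = rigid_transform())
  center <- colMeans(apply_transform(slice$transform, base_pts))
  bins <- min(settings$bins, max(8L, floor(sqrt(n_in))))
  # through-plane PSF taps: offsets along the (rotated) slice normal
  sig_z <- slice$thickness / (2 * sqrt(2 * log(2)))
  n_taps <- settings$psf_taps
  offs <- (seq_len(n_taps) - (n_taps + 1) / 2) * sig_z
  wts <- stats::dnorm(offs, 0, sig_z)
  wts <- wts / sum(wts)
  normal0 <- slice$grid$direction[, 3]
  cost <- function(par) {
    tf <- perturbed_transform(par, center, slice$transform)
    p <- apply_transform(tf, base_pts)
    if (n_taps == 1L) {
      v <- interpolate_volume(volume, p)
      ok <- is.finite(v)
      if (mean(ok) < settings$min_overlap) return(-Inf)
      return(nmi_cost(vals[ok], v[ok], bins, settings$parzen_sigma))
    }
    nrm <- as.numeric(tf$R %*% normal0)
    vsum <- numeric(nrow(p)); wsum <- numeric(nrow(p))
    for (q in seq_len(n_taps)) {
      v <- interpolate_volume(volume, sweep(p, 2L, offs[q] * nrm, `+`))
      okq <- is.finite(v)
      vsum[okq] <- vsum[okq] + wts[q] * v[okq]
      wsum[okq] <- wsum[okq] + wts[q]
    }
    ok <- wsum > 0.6
    if (mean(ok) < settings$min_overlap) return(-Inf)
    nmi_cost(vals[ok], vsum[ok] / wsum[ok], bins, settings$parzen_sigma)
  }
  fit <- pattern_search(cost, rep(0, 6), settings)
  if (!is.finite(fit$value))
    return(list(transform = slice$transform, nmi = NA_real_,
                flagged = TRUE))
  list(transform = perturbed_transform(fit$par, center, slice$transform),
       nmi = fit$value, flagged = FALSE)
}

# the 24 proper axis-aligned rotations of a cube
axis_rotation_set <- function() {
  cands <- list()
  for (rx in c(0, 90, 180, 270)) for (ry in c(0, 90, 180, 270))
    for (rz in c(0, 90, 180, 270)) {
      R <- euler_matrix(rx, ry, rz)
      dup <- any(vapply(cands, function(q) max(abs(q - R)) < 1e-9,
                        logical(1)))
      if (!dup) cands[[length(cands) + 1L]] <- R
    }
  cands
}

#' Register one stack volume to a template volume
#'
#' Multi-start (identity plus the 24 axis-aligned orientations, about
#' the mask centroid) volumetric rigid registration maximizing NMI over
#' the template's in-mask voxels; the best starts are refined by local
#' pattern search and the winner must reach the minimum overlap
#' fraction.  Returns the transform mapping template-space points to
#' the corresponding stack-space points (so the stack is brought onto
#' the template by its inverse).
#'
#' @param stack_vol moving [volume3d()] (a stack resampled as a volume).
#' @param template_vol fixed [volume3d()] with a mask.
#' @param settings a [registration_settings()].
#' @param refine_top number of best starts refined locally.
#' @return List: `transform`, `nmi`, `overlap`.
#' @export
register_stack_to_template <- function(stack_vol, template_vol,
                                       settings = registration_settings(),
                                       refine_top = 3L) {
  mask <- volume_mask(template_vol)
  pts <- grid_points(template_vol$grid)[as.vector(mask), , drop = FALSE]
  vals <- template_vol$values[mask]
  if (nrow(pts) > 20000L) {
    keep <- seq(1L, nrow(pts), length.out = 20000L)
    pts <- pts[keep, , drop = FALSE]
    vals <- vals[keep]
  }
  center <- colMeans(pts)
  score <- function(tf) {
    v <- interpolate_volume(stack_vol, apply_transform(tf, pts))
    ok <- is.finite(v)
    if (mean(ok) < settings$min_overlap) return(c(-Inf, mean(ok)))
    c(nmi_cost(vals[ok], v[ok], settings$bins, settings$parzen_sigma),
      mean(ok))
  }
  starts <- c(list(diag(3)), axis_rotation_set())
  start_tf <- lapply(starts, function(R)
    rigid_transform(R, as.numeric(center - R %*% center)))
  sc <- vapply(start_tf, function(tf) score(tf)[1], numeric(1))
  if (all(!is.finite(sc)))
    stop("stack registration failed: no start reaches the minimum overlap")
  ord <- order(sc, decreasing = TRUE)[seq_len(min(refine_top, sum(is.finite(sc))))]
  best <- NULL
  vol_settings <- settings
  vol_settings$step_mm <- max(settings$step_mm, 4)   # larger capture range
  vol_settings$step_deg <- max(settings$step_deg, 4) # for whole volumes
  for (i in ord) {
    base <- start_tf[[i]]
    fit <- pattern_search(function(par) {
      score(perturbed_transform(par, center, base))[1]
    }, rep(0, 6), vol_settings)
    if (is.null(best) || fit$value > best$value)
      best <- list(value = fit$value,
                   tf = perturbed_transform(fit$par, center, base))
  }
  if (!is.finite(best$value))
    stop("stack registration failed: no start reaches the minimum overlap")
  sc2 <- score(best$tf)
  list(transform = best$tf, nmi = sc2[1], overlap = sc2[2])
}

#' Interleaved motion correction and reconstruction
#'
#' The outer loop of the method: for each motion-correction iteration,
#' (a) register every slice to the current volume (skipped on the first
#' iteration, when no volume exists yet), (b) update the regularization
#' weight on a geometric schedule from `lambda0_factor` to
#' `lambda_final_factor`, (c) rebuild the system matrix for the new
#' transforms, (d) Gaussian-weighted initialization, (e) robust
#' super-resolution EM reconstruction.  The final iteration runs
#' `em_iterations_final` EM iterations.
#'
#' @param stacks preprocessed stacks (masked; transforms at least
#'   coarsely initialized, e.g. by stack pre-registration).
#' @param settings a [registration_settings()]; `motion_iterations`
#'   controls the loop length.
#' @param recon a [recon_settings()].
#' @param grid reconstruction grid; default [default_recon_grid()].
#' @param lambda0_factor,lambda_final_factor regularization schedule
#'   endpoints as multiples of `delta^2`.
#' @return List of class `svr_motion`: final `volume`, `stacks` (final
#'   transforms and intensity state), `recon` (last [reconstruct()]
#'   result), `trace` (per-iteration data.frame: lambda factor,
#'   objective, excluded count), `flagged` (slices skipped by
#'   registration).
#' @export
motion_correct <- function(stacks, settings = registration_settings(),
                           recon = recon_settings(), grid = NULL,
                           lambda0_factor = 0.08,
                           lambda_final_factor = 0.01) {
  stacks <- as_stack_list(stacks)
  if (is.null(grid)) grid <- default_recon_grid(stacks)
  n_it <- settings$motion_iterations
  lam <- if (n_it == 1L) lambda_final_factor else
    lambda0_factor * (lambda_final_factor / lambda0_factor)^
      ((seq_len(n_it) - 1) / (n_it - 1))
  res <- NULL
  flagged <- integer(0)
  trace <- list()
  for (it in seq_len(n_it)) {
    if (it > 1L) {
      vol <- res$volume
      stacks <- map_slices(stacks, function(sl, g) {
        fit <- register_slice_to_volume(sl, vol, settings)
        if (fit$flagged) flagged <<- union(flagged, g)
        sl$transform <- fit$transform
        sl
      })
    }
    rs <- recon
    rs$lambda_factor <- lam[it]
    iters <- if (it == n_it) recon$em_iterations_final else
      recon$em_iterations
    res <- reconstruct(stacks, grid, rs, iterations = iters)
    stacks <- res$stacks
    trace[[it]] <- data.frame(iteration = it, lambda_factor = lam[it],
                              objective = utils::tail(res$objective, 1),
                              excluded = sum(res$diagnostics$excluded))
  }
  structure(list(volume = res$volume, stacks = stacks, recon = res,
                 trace = do.call(rbind, trace), flagged = flagged),
            class = "svr_motion")
}
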