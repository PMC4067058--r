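#' Method-variant table for the ablation bench
#'
#' The five reconstruction variants compared throughout the evaluation:
#' \tabular{lll}{
#'   variant \tab robust statistics \tab intensity matching \cr
#'   full \tab EM \tab yes \cr
#'   huber \tab Huber \tab yes \cr
#'   no_robust \tab none \tab yes \cr
#'   no_matching \tab EM \tab no \cr
#'   reference \tab EM \tab no (inputs carry no scale/bias corruption) \cr
#' }
#'
#' @param variant variant name.
#' @param base a [recon_settings()] supplying everything else.
#' @return A [recon_settings()] with the variant's flags applied.
#' @export
variant_settings <- function(variant = c("full", "huber", "no_robust",
                                         "no_matching", "reference"),
                             base = recon_settings()) {
  variant <- match.arg(variant)
  base$use_robust <- switch(variant, full = "em", huber = "huber",
                            no_robust = "none", no_matching = "em",
                            reference = "em")
  base$use_intensity_matching <- variant %in% c("full", "huber", "no_robust")
  base
}

#' Run the ablation bench on simulated acquisitions
#'
#' For each seed, simulates one corrupted acquisition (and a matched
#' intensity-clean acquisition for the reference variant: same motion,
#' outliers and noise, but no scales or bias fields, thanks to the
#' simulator's independent sub-seeds), reconstructs it with each
#' requested variant, and scores NRMSE, PSNR and TRE against the ground
#' truth.  TRE composes the estimated transforms with the best-fit
#' common rigid transform onto the truth (the reconstruction-to-original
#' alignment step of the evaluation protocol, computed in closed form by
#' Procrustes instead of an extra image registration).
#'
#' @param phantom ground-truth [volume3d()]; default [make_phantom()].
#' @param spec base [simulation_spec()]; its seed is replaced per run.
#' @param seeds integer vector of simulation seeds.
#' @param variants subset of the five variant names.
#' @param recon base [recon_settings()].
#' @param reg [registration_settings()]; `motion_iterations` controls
#'   the motion-correction effort per run.
#' @param known_transforms hand the true transforms to the
#'   reconstructor and skip motion correction (fast known-alignment
#'   mode).
#' @return List: `results` (data.frame: seed, variant, nrmse, psnr,
#'   tre_mm), `details` (per run: diagnostics, labels, slice
#'   posteriors).
#' @export
run_ablation_bench <- function(phantom = make_phantom(),
                               spec = simulation_spec(),
                               seeds = 1:3,
                               variants = c("full", "huber", "no_robust",
                                            "no_matching", "reference"),
                               recon = recon_settings(),
                               reg = registration_settings(motion_iterations = 3L),
                               known_transforms = FALSE) {
  rows <- list()
  details <- list()
  for (sd in seeds) {
    sp <- spec
    sp$seed <- as.integer(sd)
    sim <- simulate_acquisition(phantom, sp)
    sp_clean <- sp
    sp_clean$bias_amplitude <- 0
    sp_clean$scale_range <- c(1, 1)
    sim_clean <- simulate_acquisition(phantom, sp_clean)
    for (v in variants) {
      use <- if (v == "reference") sim_clean else sim
      stacks <- transfer_mask(use$stacks, phantom)
      rs <- variant_settings(v, recon)
      if (known_transforms) {
        stacks <- transfer_mask(apply_true_transforms(use$stacks, use$truth),
                                phantom)
        res <- reconstruct(stacks, phantom$grid, rs)
        est_stacks <- res$stacks
        last <- res
      } else {
        mc <- motion_correct(stacks, reg, rs, grid = phantom$grid)
        est_stacks <- mc$stacks
        last <- mc$recon
      }
      matched <- match_to_reference(last$volume, phantom, register = FALSE)
      slices <- all_slices(est_stacks)
      pts <- lapply(slices, function(s)
        slice_points(s, transform = rigid_transform()))
      est_tf <- lapply(slices, `[[`, "transform")
      tr <- tre(gauge_align(est_tf, use$truth$transforms, pts,
                            use$truth$labels),
                use$truth$transforms, pts, use$truth$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd, variant = v,
        nrmse = nrmse(matched, phantom), psnr = psnr(matched, phantom),
        tre_mm = tr$mean_mm)
      details[[paste(sd, v, sep = "_")]] <- list(
        diagnostics = last$diagnostics, labels = use$truth$labels,
        objective = last$objective)
    }
  }
  list(results = do.call(rbind, rows), details = details)
}

#' Best-fit common rigid gauge between two transform sets
#'
#' Composes every estimated transform with the single rigid transform
#' (closed-form Procrustes/Kabsch over the included slices' voxel
#' positions) that best aligns the estimated with the true positions —
#' the desk-scale equivalent of registering the reconstructed volume to
#' the original before computing TRE.
#'
#' @param est,truth lists of [rigid_transform()].
#' @param points list of per-slice voxel position matrices.
#' @param labels slice labels; only `"clean"` slices (with >= `min_roi`
#'   voxels) drive the fit.
#' @param min_roi minimum voxel count.
#' @return `est` with the common gauge composed in front.
#' @export
gauge_align <- function(est, truth, points, labels = rep("clean", length(est)),
                        min_roi = 50L) {
  use <- which(labels == "clean" &
                 vapply(points, nrow, integer(1)) >= min_roi)
  if (!length(use)) return(est)
  A <- do.call(rbind, lapply(use, function(k)
    apply_transform(est[[k]], points[[k]])))
  B <- do.call(rbind, lapply(use, function(k)
    apply_transform(truth[[k]], points[[k]])))
  ca <- colMeans(A); cb <- colMeans(B)
  s <- svd(crossprod(sweep(A, 2, ca), sweep(B, 2, cb)))
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  G <- rigid_transform(R, cb - as.numeric(R %*% ca))
  lapply(est, function(tf) compose(G, tf))
}
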