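#' Bias-field estimation settings
#'
#' @param sigma smoothness of the differential bias field in mm
#'   (Gaussian kernel standard deviation; default 12 mm).
#' @param enabled logical; bias estimation can be switched off while
#'   keeping scale estimation.
#' @return An object of class `bias_settings`.
#' @export
bias_settings <- function(sigma = 12, enabled = TRUE) {
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  structure(list(sigma = sigma, enabled = isTRUE(enabled)),
            class = "bias_settings")
}

#' Per-slice scale update
#'
#' Exact minimizer of the robust objective in the scales:
#' `s_k = sum_j p exp(-b) y yhat / sum_j p (exp(-b) y)^2`, followed by
#' the gauge fix multiplying all scales by a constant so their product is
#' 1 (otherwise the overall image intensity drifts toward zero across
#' iterations).  Slices whose denominator vanishes keep their previous
#' scale (with a warning) and still take part in the renormalization.
#'
#' @param y acquired intensities (flat vector over in-mask slice voxels).
#' @param simulated simulated intensities `yhat = M x` (same layout; `NA`
#'   entries are skipped).
#' @param posteriors voxel inlier posteriors p_jk (same layout).
#' @param bias current log-bias values b_jk (same layout).
#' @param slice integer slice id per entry.
#' @param n_slices total slice count.
#' @param prev_scales scales to fall back on, length `n_slices`.
#' @return List: `scales` (renormalized, product 1), `raw` (before the
#'   gauge fix).
#' @export
update_scales <- function(y, simulated, posteriors, bias, slice, n_slices,
                          prev_scales = rep(1, n_slices)) {
  ok <- !is.na(simulated)
  eb_y <- exp(-bias[ok]) * y[ok]
  p <- posteriors[ok]
  agg <- rowsum(cbind(p * eb_y * simulated[ok], p * eb_y^2), slice[ok])
  ids <- as.integer(rownames(agg))
  raw <- prev_scales
  good <- agg[, 2] > 0 & is.finite(agg[, 1] / agg[, 2]) &
    agg[, 1] / agg[, 2] > 0
  if (!all(good)) warning("slices with degenerate scale update keep previous scale")
  raw[ids[good]] <- agg[good, 1] / agg[good, 2]
  # gauge: product of all scales equals one (geometric renormalization)
  g <- exp(mean(log(raw)))
  list(scales = raw / g, raw = raw)
}

#' Differential bias-field update for one slice
#'
#' Multiplicative-exponential bias model: the residual still present in
#' the corrected slice is \code{r = log(y*/yhat)} (voxels with non-positive
#' `y*` or `yhat` are skipped), and the bias increment is the weighted
#' Gaussian smoothing of `r` with weights `w = y* p`, computed as a ratio
#' of truncated-kernel convolutions `conv(w r, G) / conv(w, G)` over the
#' slice plane.  The per-slice zero-mean constraint over in-mask voxels
#' is enforced afterwards (a constant log-bias is the scale's job).
#'
#' @param slice an [mri_slice()] (its `bias`, `scale`, `mask` are used).
#' @param simulated matrix of simulated intensities for this slice (`NA`
#'   where the forward model has no support).
#' @param posteriors matrix of voxel posteriors for this slice.
#' @param settings a [bias_settings()].
#' @return The slice with updated `bias`.
#' @export
update_bias <- function(slice, simulated, posteriors, settings) {
  if (!settings$enabled) return(slice)
  ystar <- corrected_values(slice)
  valid <- slice$mask & !is.na(simulated) & ystar > 0 & simulated > 0
  if (!any(valid)) return(slice)
  r <- matrix(0, nrow(ystar), ncol(ystar))
  r[valid] <- log(ystar[valid] / simulated[valid])
  w <- matrix(0, nrow(ystar), ncol(ystar))
  w[valid] <- ystar[valid] * posteriors[valid]
  if (all(w == 0)) return(slice)
  sigma_px <- settings$sigma / slice$grid$spacing[1:2]
  inc <- gauss_smooth2d_weighted(r, w, sigma_px)
  inc[is.na(inc)] <- 0
  b <- slice$bias + inc
  b <- b - mean(b[slice$mask])   # zero mean over in-mask voxels
  slice$bias <- b
  slice
}

# Robust intensity-matching objective F(S, B) = sum pslice p e^2 used by
# the monotonicity tests; flat layout.
intensity_objective <- function(y, simulated, posteriors, slice_post,
                                bias, scales, slice) {
  ok <- !is.na(simulated)
  e <- scales[slice[ok]] * exp(-bias[ok]) * y[ok] - simulated[ok]
  sum(slice_post[slice[ok]] * posteriors[ok] * e^2)
}
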