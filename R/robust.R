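#' Voxel-level robust model (Gaussian inliers + uniform outliers)
#'
#' The residuals e_jk between corrected and simulated slice intensities
#' are modeled as a mixture of a zero-mean Gaussian (inliers, variance
#' `sigma2`, mixing proportion `c`) and a uniform outlier density `m`.
#'
#' @param sigma2 inlier variance (> 0).
#' @param c inlier mixing proportion in \[0, 1\].
#' @param m uniform outlier density (> 0).
#' @return An object of class `voxel_robust_model`.
#' @export
voxel_robust_model <- function(sigma2, c, m) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("'sigma2' must be positive")
  if (c < 0 || c > 1) stop("'c' must lie in [0, 1]")
  if (!is.finite(m) || m <= 0) stop("'m' must be positive")
  structure(list(sigma2 = sigma2, c = c, m = m),
            class = "voxel_robust_model")
}

gauss_density <- function(e, sigma2) {
  exp(-e^2 / (2 * sigma2)) / sqrt(2 * pi * sigma2)
}

#' Posterior inlier probabilities of voxel errors
#'
#' `p_jk = G(e) c / (G(e) c + m (1 - c))`, a redescending weighting:
#' `e * p(e) -> 0` as `|e| -> Inf`.
#'
#' @param errors numeric vector of residuals e_jk.
#' @param model a [voxel_robust_model()].
#' @return Posteriors in \[0, 1\], same length as `errors`.
#' @export
voxel_posteriors <- function(errors, model) {
  g <- gauss_density(errors, model$sigma2) * model$c
  out <- g / (g + model$m * (1 - model$c))
  out[model$c == 0] <- 0
  out
}

#' M-step update of the voxel robust model
#'
#' `sigma2 = sum(p e^2) / sum(p)` and `c = sum(p) / n`; the uniform
#' density `m` is held fixed.  `sigma2` is floored at
#' `(1e-6 * intensity_scale)^2` to avoid posterior collapse on degenerate
#' (noise-free) residuals.
#'
#' @param errors residuals e_jk.
#' @param posteriors current inlier posteriors p_jk.
#' @param model current [voxel_robust_model()] (supplies `m`).
#' @param intensity_scale typical intensity magnitude used for the
#'   variance floor.
#' @return Updated [voxel_robust_model()].
#' @export
update_voxel_model <- function(errors, posteriors, model,
                               intensity_scale = 1) {
  sp <- sum(posteriors)
  if (sp <= 0) stop("degenerate robust model: all posteriors are zero")
  sigma2 <- sum(posteriors * errors^2) / sp
  sigma2 <- max(sigma2, (1e-6 * intensity_scale)^2)
  cc <- min(1, sp / length(errors))
  voxel_robust_model(sigma2, cc, model$m)
}

#' Uniform outlier density from the error range
#'
#' `m = 1 / (max(e) - min(e))`; a zero range falls back to
#' `1 / eps_range` with `eps_range = 1e-6`.
#'
#' @param errors residuals.
#' @return Scalar density `m`.
#' @export
init_uniform_density <- function(errors) {
  if (!length(errors)) stop("empty errors")
  rng <- max(errors) - min(errors)
  if (rng <= 0) rng <- 1e-6
  1 / rng
}

# Observed-data log-likelihood of the voxel mixture (monotonicity checks)
voxel_loglik <- function(errors, model) {
  sum(log(gauss_density(errors, model$sigma2) * model$c +
            model$m * (1 - model$c)))
}

#' Per-slice inlier potentials
#'
#' `(sum_j p_jk^2) / N_k` over the in-mask voxels of each slice; values
#' near 1 indicate agreement with the volume.
#'
#' @param posteriors voxel posteriors (flat vector).
#' @param slice integer slice id per entry of `posteriors`.
#' @param n_slices total number of slices.
#' @return Numeric vector of length `n_slices`; slices with no voxels get
#'   `NA` (and a warning).
#' @export
slice_potentials <- function(posteriors, slice, n_slices) {
  stopifnot(length(posteriors) == length(slice))
  num <- rep(0, n_slices); den <- rep(0, n_slices)
  agg <- rowsum(cbind(posteriors^2, 1), slice)
  ids <- as.integer(rownames(agg))
  num[ids] <- agg[, 1]; den[ids] <- agg[, 2]
  out <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(out)) warning("slices with no in-mask voxels excluded")
  out
}

#' Slice inlier posteriors via a two-Gaussian EM
#'
#' A 1-D mixture of two Gaussians is fitted to the slice potentials by
#' EM (initialized by a median split, at most `max_iter` iterations,
#' likelihood tolerance `tol`); the component with the larger mean is the
#' inlier class and its responsibilities are the slice posteriors
#' p_k^slice.  Identical potentials mean there is nothing to classify:
#' all slices are inliers.
#'
#' @param potentials per-slice potentials from [slice_potentials()]
#'   (`NA` entries get posterior 0).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return Posteriors in \[0, 1\] per slice.
#' @export
slice_posteriors <- function(potentials, max_iter = 50L, tol = 1e-8) {
  out <- rep(0, length(potentials))
  ok <- which(!is.na(potentials))
  x <- potentials[ok]
  if (length(x) < 2L || max(x) - min(x) < 1e-12) {
    out[ok] <- 1
    return(out)
  }
  med <- stats::median(x)
  hi <- x >= med
  if (!any(hi) || all(hi)) hi <- x >= mean(range(x))
  mu <- c(mean(x[!hi]), mean(x[hi]))
  v <- c(stats::var(x[!hi]), stats::var(x[hi]))
  v[!is.finite(v) | v < 1e-8] <- 1e-8
  w <- c(mean(!hi), mean(hi))
  w[w < 1e-6] <- 1e-6; w <- w / sum(w)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(v[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(v[2]))
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    w <- c(mean(1 - r2), mean(r2))
    w[w < 1e-6] <- 1e-6; w <- w / sum(w)
    mu <- c(sum((1 - r2) * x) / sum(1 - r2), sum(r2 * x) / sum(r2))
    v <- c(sum((1 - r2) * (x - mu[1])^2) / sum(1 - r2),
           sum(r2 * (x - mu[2])^2) / sum(r2))
    v[!is.finite(v) | v < 1e-8] <- 1e-8
  }
  # inlier class = larger mean
  out[ok] <- if (mu[2] >= mu[1]) r2 else 1 - r2
  out
}

#' Huber weights (non-redescending alternative)
#'
#' `p = 1` for `|e| <= gamma`, `gamma / |e|` otherwise.
#'
#' @param errors residuals.
#' @param gamma threshold; default `1.35 * median(|errors|)`.
#' @return Weights in (0, 1\].
#' @export
huber_weights <- function(errors, gamma = 1.35 * stats::median(abs(errors))) {
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be positive")
  ae <- abs(errors)
  ifelse(ae <= gamma, 1, gamma / ae)
}
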