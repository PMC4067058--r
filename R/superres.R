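#' Reconstruction settings
#'
#' Controls the super-resolution EM loop.  The regularization weight is
#' specified as a multiple of `delta^2` (`lambda = lambda_factor *
#' delta^2`), matching the reported operating range: 0.16 or 0.08 for the
#' first motion-correction iteration, decaying to 0.02-0.005 for the
#' final one; the defaults here are 0.08 down to 0.01 on a geometric
#' schedule handled by [motion_correct()].
#'
#' @param alpha gradient step (relaxation factor in `"normalized"` step
#'   mode); `NULL` defaults to 0.9.
#' @param step_mode `"normalized"` (default) divides the back-projected
#'   correction by the per-voxel confidence `sum_kj p^slice p_jk m_ijk`
#'   before applying `alpha` — a weighted-Jacobi step that converges in
#'   a few iterations; `"global"` applies the plain gradient step
#'   `x_i <- x_i + alpha sum_kj p^slice p m e` with
#'   `alpha = 0.9 / max_i(confidence)` when `alpha` is `NULL` (the
#'   literal update equation, much smaller steps).
#' @param lambda_factor regularization weight as a multiple of `delta^2`.
#' @param delta edge threshold intensity; `NULL` estimates it from the
#'   initialized volume as half the distance between the two dominant
#'   tissue modes of its in-mask histogram.
#' @param em_iterations EM iterations per motion-correction iteration.
#' @param em_iterations_final EM iterations of the final reconstruction.
#' @param use_robust one of `"em"` (Gaussian+uniform voxel mixture and
#'   two-Gaussian slice classification), `"huber"`, `"none"`.
#' @param use_intensity_matching estimate per-slice scales and bias
#'   fields during reconstruction.
#' @param bias a [bias_settings()].
#' @param slice_post_in_model if TRUE slice posteriors also weight the
#'   voxel-model M-step sums (off by default; voxel posteriors only).
#' @return An object of class `recon_settings`.
#' @export
recon_settings <- function(alpha = NULL, lambda_factor = 0.02, delta = NULL,
                           em_iterations = 10L, em_iterations_final = 30L,
                           use_robust = c("em", "huber", "none"),
                           use_intensity_matching = TRUE,
                           bias = bias_settings(),
                           step_mode = c("normalized", "global"),
                           slice_post_in_model = FALSE) {
  use_robust <- match.arg(use_robust)
  step_mode <- match.arg(step_mode)
  stopifnot(is.null(alpha) || alpha > 0, lambda_factor >= 0,
            is.null(delta) || delta > 0,
            em_iterations >= 1L, em_iterations_final >= 1L)
  structure(list(alpha = alpha, lambda_factor = lambda_factor,
                 delta = delta, em_iterations = as.integer(em_iterations),
                 em_iterations_final = as.integer(em_iterations_final),
                 use_robust = use_robust,
                 use_intensity_matching = isTRUE(use_intensity_matching),
                 bias = bias, step_mode = step_mode,
                 slice_post_in_model = isTRUE(slice_post_in_model)),
            class = "recon_settings")
}

#' Gaussian-weighted reconstruction (initialization)
#'
#' PSF-weighted averaging of the corrected slice intensities onto the
#' volume grid: `x_i = sum_jk m_ijk y*_jk / sum_jk m_ijk`.  Voxels with
#' no PSF support are filled by iterative nearest-neighbor dilation from
#' the covered region and flagged in the returned `uncovered` array.
#'
#' @param M a [build_system_matrix()] result.
#' @param y corrected slice intensities, one value per system-matrix row
#'   (`NA` entries and empty rows are skipped).
#' @return List: `volume` ([volume3d()]), `weights` (per-voxel total PSF
#'   weight), `uncovered` (logical array).
#' @export
gaussian_weighted_init <- function(M, y) {
  use <- !M$empty & !is.na(y)
  if (!any(use)) stop("no slice data covers the reconstruction grid")
  yy <- y; yy[!use] <- 0
  num <- as.vector(Matrix::crossprod(M$M, yy * use))
  den <- as.vector(Matrix::crossprod(M$M, as.numeric(use)))
  x <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), NA_real_)
  arr <- array(x, M$grid$shape)
  uncovered <- is.na(arr)
  arr <- nn_fill(arr)
  list(volume = volume3d(arr, M$grid),
       weights = array(den, M$grid$shape), uncovered = uncovered)
}

# iterative 6-neighbor mean fill of NA voxels (nearest-covered fill)
nn_fill <- function(arr) {
  d <- dim(arr)
  while (anyNA(arr)) {
    na_idx <- which(is.na(arr))
    ijk <- arrayInd(na_idx, d)
    acc <- numeric(length(na_idx)); cnt <- numeric(length(na_idx))
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[, axis] <- nb[, axis] + s
      ok <- nb[, axis] >= 1L & nb[, axis] <= d[axis]
      lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
      v <- arr[lin]
      has <- !is.na(v)
      w <- which(ok)[has]
      acc[w] <- acc[w] + v[has]
      cnt[w] <- cnt[w] + 1
    }
    fill <- cnt > 0
    if (!any(fill)) { arr[na_idx] <- 0; break }  # fully disconnected
    arr[na_idx[fill]] <- acc[fill] / cnt[fill]
  }
  arr
}

# 26-neighborhood offsets with Euclidean lengths
neighbor_offsets <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  list(offsets = d, len = sqrt(rowSums(d^2)))
}

# shift a 3-D array by integer offset, NA outside
shift_array <- function(arr, off) {
  d <- dim(arr)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) + off[a]
    i[i < 1L | i > d[a]] <- NA_integer_
    i
  })
  out <- array(NA_real_, d)
  ok <- lapply(src, function(i) !is.na(i))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    arr[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

#' Edge-preserving regularization gradient
#'
#' The descent direction of the edge-preserving roughness penalty
#' `R(X) = sum_i sum_d phi((x_{i+d} - x_i) / (delta sqrt(|d|)))` with
#' `phi(t) = 2 sqrt(1 + t^2) - 2` over the 26-neighborhood:
#' `D_i = (1/delta^2) sum_d b_id (x_{i+d} - x_i)` with
#' `b_id = 1 / (|d| sqrt(1 + ((x_{i+d} - x_i) / (delta sqrt(|d|)))^2))`.
#' Boundary voxels use only in-grid neighbors.  Up to the positive
#' constant folded into the regularization weight, `D = -grad R / 4`.
#'
#' @param values 3D numeric array (or [volume3d()]).
#' @param delta edge threshold intensity.
#' @return 3D array of per-voxel descent directions.
#' @export
regularizer_gradient <- function(values, delta) {
  if (inherits(values, "volume3d")) values <- values$values
  if (delta <= 0) stop("'delta' must be positive")
  nb <- neighbor_offsets()
  out <- array(0, dim(values))
  for (q in seq_len(nrow(nb$offsets))) {
    xd <- shift_array(values, nb$offsets[q, ])
    diffv <- xd - values
    b <- 1 / (nb$len[q] * sqrt(1 + (diffv / (delta * sqrt(nb$len[q])))^2))
    contrib <- b * diffv
    contrib[is.na(contrib)] <- 0
    out <- out + contrib
  }
  out / delta^2
}

# roughness penalty R(X) itself (finite-difference oracle target)
regularizer_value <- function(values, delta) {
  nb <- neighbor_offsets()
  tot <- 0
  for (q in seq_len(nrow(nb$offsets))) {
    xd <- shift_array(values, nb$offsets[q, ])
    t2 <- ((xd - values) / (delta * sqrt(nb$len[q])))^2
    phi <- 2 * sqrt(1 + t2) - 2
    tot <- tot + sum(phi, na.rm = TRUE)
  }
  tot
}

# Confidence-weighted edge-preserving smoothing: implicit local update
#   x_i <- [c_i x_i + k sum_d b_id c_{i+d} x_{i+d}] /
#          [c_i + k sum_d b_id c_{i+d}],   k = alpha * lambda / delta^2
# with c the normalized voxel confidence sum_kj p^slice p m_ijk.  Where
# c_i = 0 the data term vanishes and the voxel is inpainted entirely
# from its neighbors (full regularization); where the whole neighborhood
# has zero confidence the voxel is kept.
edge_smooth <- function(values, conf, k, delta) {
  if (k <= 0) return(values)
  nb <- neighbor_offsets()
  num <- conf * values
  den <- conf
  for (q in seq_len(nrow(nb$offsets))) {
    xd <- shift_array(values, nb$offsets[q, ])
    cd <- shift_array(conf, nb$offsets[q, ])
    b <- 1 / (nb$len[q] * sqrt(1 + ((xd - values) / (delta * sqrt(nb$len[q])))^2))
    w <- k * b * cd
    w[is.na(w)] <- 0
    xd[is.na(xd)] <- 0
    num <- num + w * xd
    den <- den + w
  }
  out <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), values)
  array(out, dim(values))
}

#' Estimate the edge threshold delta from a volume
#'
#' Half the distance between the two dominant modes of the smoothed
#' in-mask intensity histogram (gray/white matter analog); falls back to
#' 0.15 x intensity range when fewer than two modes are found.
#'
#' @param values numeric vector or array of intensities.
#' @param mask optional logical selection.
#' @return Scalar delta.
#' @export
estimate_delta <- function(values, mask = NULL) {
  v <- if (is.null(mask)) as.vector(values) else values[mask]
  v <- v[is.finite(v)]
  if (length(v) < 10L || max(v) - min(v) <= 0) return(1)
  dens <- stats::density(v, n = 512)
  y <- dens$y
  pk <- which(y > c(y[-1], -Inf) & y > c(-Inf, y[-length(y)]))
  if (length(pk) >= 2L) {
    top <- pk[order(y[pk], decreasing = TRUE)[1:2]]
    d <- abs(diff(dens$x[top])) / 2
    if (d > 1e-6 * (max(v) - min(v))) return(d)
  }
  0.15 * (max(v) - min(v))
}

#' One robust super-resolution volume update
#'
#' The data step `x_i <- x_i + alpha sum_kj p_k^slice p_jk m_ijk e_jk`
#' followed by confidence-weighted edge-preserving smoothing.  With all
#' posteriors 1 and `lambda = 0` this is exactly the classical
#' super-resolution gradient step.
#'
#' @param x current volume values (flat vector over grid voxels).
#' @param M a [build_system_matrix()] result.
#' @param errors residuals `y* - M x` per row (`NA` rows are skipped).
#' @param posteriors voxel posteriors per row.
#' @param slice_post slice posteriors (per slice id).
#' @param settings a [recon_settings()] with resolved `delta`.
#' @param lambda_factor regularization weight as multiple of `delta^2`.
#' @return List: `x` updated values, `alpha` the step used, `conf` the
#'   per-voxel confidence vector.
#' @export
sr_update <- function(x, M, errors, posteriors, slice_post, settings,
                      lambda_factor = settings$lambda_factor) {
  ok <- !is.na(errors)
  w <- posteriors * slice_post[M$rows$slice]
  we <- ifelse(ok, w * errors, 0)
  conf <- as.vector(Matrix::crossprod(M$M, ifelse(ok, w, 0)))
  addon <- as.vector(Matrix::crossprod(M$M, we))
  alpha <- settings$alpha
  if (identical(settings$step_mode, "global")) {
    if (is.null(alpha)) {
      mx <- max(conf)
      alpha <- if (mx > 0) 0.9 / mx else 1
    }
    x <- x + alpha * addon
  } else {
    if (is.null(alpha)) alpha <- 0.9
    pos <- conf > 0
    addon[pos] <- addon[pos] / conf[pos]
    x <- x + alpha * addon
  }
  if (lambda_factor > 0) {
    cmax <- max(conf)
    cn <- if (cmax > 0) conf / cmax else conf
    k <- alpha * lambda_factor   # alpha * lambda / delta^2
    x <- as.vector(edge_smooth(array(x, M$grid$shape),
                               array(cn, M$grid$shape), k,
                               settings$delta))
  }
  list(x = x, alpha = alpha, conf = conf)
}

#' Robust super-resolution EM reconstruction (fixed alignment)
#'
#' Runs the per-motion-iteration EM loop: simulate slices, compute
#' errors, voxel posteriors and robust-model update, slice potentials
#' and two-Gaussian slice classification, scale and bias updates, then
#' the super-resolution volume update with confidence-weighted
#' edge-preserving smoothing.  Slice transforms are taken as given;
#' interleaving with registration lives in [motion_correct()].
#'
#' @param stacks a [slice_stack()] or list of stacks (masks and current
#'   transforms are used; scale/bias state carries over unless `reset`).
#' @param grid reconstruction [image_grid()]; see
#'   [default_recon_grid()].
#' @param settings a [recon_settings()].
#' @param M optional precomputed [build_system_matrix()] (rebuilt
#'   otherwise); must match the current slice transforms.
#' @param iterations EM iteration count; defaults to
#'   `settings$em_iterations`.
#' @param x0 optional initial volume values; defaults to
#'   [gaussian_weighted_init()].
#' @param reset reset scales/biases/posteriors before starting (default
#'   TRUE).
#' @return List of class `svr_recon`: `volume`, `stacks` (with final
#'   intensity state and posteriors), `diagnostics` (data.frame per
#'   slice: scale, potential, slice posterior, excluded), `objective`
#'   (per-iteration robust data term), `model`, `settings` (with
#'   resolved `delta`), `M`.
#' @export
reconstruct <- function(stacks, grid, settings = recon_settings(),
                        M = NULL, iterations = settings$em_iterations,
                        x0 = NULL, reset = TRUE) {
  stacks <- as_stack_list(stacks)
  if (reset)
    stacks <- map_slices(stacks, function(sl, g) {
      sl$scale <- 1
      sl$bias[] <- 0
      sl$posteriors[] <- 1
      sl$slice_posterior <- 1
      sl$excluded <- FALSE
      sl
    })
  if (is.null(M)) M <- build_system_matrix(stacks, grid)
  rows <- M$rows
  slices <- all_slices(stacks)
  n_slices <- length(slices)
  y <- extract_rows(slices, rows, "values")
  scales <- vapply(slices, `[[`, numeric(1), "scale")
  bias <- extract_rows(slices, rows, "bias")

  init <- gaussian_weighted_init(M, scales[rows$slice] * exp(-bias) * y)
  x <- if (is.null(x0)) as.vector(init$volume$values) else as.numeric(x0)
  if (is.null(settings$delta))
    settings$delta <- estimate_delta(init$volume$values,
                                     array(init$weights > 0, grid$shape))
  intensity_scale <- mean(abs(x))
  model <- NULL
  p <- rep(1, nrow(rows))
  slice_post <- rep(1, n_slices)
  objective <- numeric(0)
  for (it in seq_len(iterations)) {
    ystar <- scales[rows$slice] * exp(-bias) * y
    yhat <- simulate_slices(x, M)
    ok <- !is.na(yhat)
    e <- ystar - yhat

    # ---- robust statistics ----------------------------------------
    if (settings$use_robust == "em") {
      if (is.null(model))
        model <- voxel_robust_model(max(mean(e[ok]^2),
                                        (1e-6 * intensity_scale)^2),
                                    0.9, init_uniform_density(e[ok]))
      p[ok] <- voxel_posteriors(e[ok], model)
      p[!ok] <- 0
      mw <- if (settings$slice_post_in_model)
        p[ok] * slice_post[rows$slice[ok]] else p[ok]
      model <- update_voxel_model(e[ok], mw, model, intensity_scale)
      pot <- suppressWarnings(
        slice_potentials(p[ok], rows$slice[ok], n_slices))
      slice_post <- slice_posteriors(pot)
    } else if (settings$use_robust == "huber") {
      gam <- 1.35 * stats::median(abs(e[ok]))
      p[ok] <- if (gam > 0) huber_weights(e[ok], gam) else 1
      p[!ok] <- 0
      rms <- sqrt(pmax(0, rowsum_safe(e[ok]^2, rows$slice[ok], n_slices,
                                      mean = TRUE)))
      gs <- 1.35 * stats::median(rms[rms > 0], na.rm = TRUE)
      slice_post <- if (is.finite(gs) && gs > 0)
        ifelse(is.na(rms) | rms <= gs, 1, gs / rms) else rep(1, n_slices)
      pot <- rms
    } else {
      p[ok] <- 1; p[!ok] <- 0
      slice_post <- rep(1, n_slices)
      pot <- rep(1, n_slices)
    }

    # ---- intensity matching ---------------------------------------
    if (settings$use_intensity_matching) {
      # routine at stack edges / fully down-weighted slices: keep the
      # previous scale quietly inside the EM loop
      up <- suppressWarnings(
        update_scales(y, yhat, p, bias, rows$slice, n_slices, scales))
      scales <- up$scales
      if (settings$bias$enabled) {
        for (s_id in seq_len(n_slices)) {
          sel <- rows$slice == s_id
          if (!any(sel)) next
          sl <- slices[[s_id]]
          sl$scale <- scales[s_id]
          sim <- matrix(NA_real_, nrow(sl$values), ncol(sl$values))
          sim[rows$pixel[sel]] <- yhat[sel]
          pm <- matrix(0, nrow(sl$values), ncol(sl$values))
          pm[rows$pixel[sel]] <- p[sel]
          sl <- update_bias(sl, sim, pm, settings$bias)
          slices[[s_id]] <- sl
        }
        bias <- extract_rows(slices, rows, "bias")
      }
      ystar <- scales[rows$slice] * exp(-bias) * y
      e <- ystar - yhat
    }

    objective <- c(objective,
                   sum((slice_post[rows$slice] * p * e^2)[ok]))
    if (length(objective) > 1 &&
        objective[length(objective)] > 10 * min(objective))
      stop("reconstruction diverged: robust data term grew 10x from its minimum")

    # ---- super-resolution update + smoothing ----------------------
    upd <- sr_update(x, M, ifelse(ok, e, NA_real_), p, slice_post, settings)
    x <- upd$x
  }

  # write state back to slices/stacks
  excluded <- slice_post < 0.5
  for (s_id in seq_len(n_slices)) {
    sel <- rows$slice == s_id
    sl <- slices[[s_id]]
    sl$scale <- scales[s_id]
    sl$posteriors[] <- 0
    sl$posteriors[rows$pixel[sel]] <- p[sel]
    sl$slice_posterior <- slice_post[s_id]
    sl$excluded <- excluded[s_id]
    slices[[s_id]] <- sl
  }
  stacks <- map_slices(stacks, function(sl, g) slices[[g]])
  diag_df <- data.frame(slice = seq_len(n_slices),
                        scale = scales, potential = pot,
                        slice_posterior = slice_post, excluded = excluded)
  vol <- volume3d(array(x, grid$shape), grid,
                  mask = array(as.vector(Matrix::crossprod(
                    M$M, rep(1, nrow(rows)))) > 0, grid$shape))
  structure(list(volume = vol, stacks = stacks, diagnostics = diag_df,
                 objective = objective, model = model,
                 settings = settings, M = M),
            class = "svr_recon")
}

# flat extraction of a per-slice matrix field along system-matrix rows
extract_rows <- function(slices, rows, field) {
  out <- numeric(nrow(rows))
  for (s_id in unique(rows$slice)) {
    sel <- rows$slice == s_id
    out[sel] <- slices[[s_id]][[field]][rows$pixel[sel]]
  }
  out
}

rowsum_safe <- function(v, g, n, mean = FALSE) {
  out <- rep(NA_real_, n)
  agg <- rowsum(cbind(v, 1), g)
  ids <- as.integer(rownames(agg))
  out[ids] <- if (mean) agg[, 1] / agg[, 2] else agg[, 1]
  out
}

#' Default isotropic reconstruction grid for a set of stacks
#'
#' Isotropic voxel size equal to the smallest in-plane spacing over the
#' stacks; extent the world bounding box of the in-mask slice voxels
#' padded by `pad` voxels, axis-aligned in world space.
#'
#' @param stacks stacks to cover.
#' @param spacing override the voxel size in mm.
#' @param pad padding in voxels.
#' @return An [image_grid()].
#' @export
default_recon_grid <- function(stacks, spacing = NULL, pad = 5L) {
  stacks <- as_stack_list(stacks)
  if (is.null(spacing))
    spacing <- min(vapply(stacks, function(s) min(s$inplane), numeric(1)))
  pts <- do.call(rbind, lapply(all_slices(stacks), function(sl)
    if (any(sl$mask)) slice_points(sl) else NULL))
  if (is.null(pts)) stop("no in-mask slice voxels")
  lo <- apply(pts, 2L, min) - pad * spacing
  hi <- apply(pts, 2L, max) + pad * spacing
  shape <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  image_grid(shape, rep(spacing, 3), origin = lo)
}
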