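# Small numeric helpers shared across modules.

# 1-D Gaussian convolution matrix with edge renormalization (kernel mass
# truncated at the boundary is renormalized, so constants are preserved).
gauss_conv_matrix <- function(n, sigma_px, truncation = 4) {
  if (sigma_px <= 0) return(diag(n))
  r <- max(1L, ceiling(truncation * sigma_px))
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-0.5 * (d / sigma_px)^2)
  K[abs(d) > r] <- 0
  K / rowSums(K)
}

# Separable Gaussian smoothing of a 2-D matrix, sigma in pixels per axis.
gauss_smooth2d <- function(mat, sigma_px) {
  sigma_px <- rep(sigma_px, length.out = 2L)
  K1 <- gauss_conv_matrix(nrow(mat), sigma_px[1])
  K2 <- gauss_conv_matrix(ncol(mat), sigma_px[2])
  K1 %*% mat %*% t(K2)
}

# 1-D Gaussian convolution band matrix WITHOUT edge renormalization
# (equivalent to zero padding); kernel normalized to unit sum in the
# interior.
gauss_band_matrix <- function(n, sigma_px, truncation = 4) {
  if (sigma_px <= 0) return(diag(n))
  r <- max(1L, ceiling(truncation * sigma_px))
  k <- exp(-0.5 * ((-r:r) / sigma_px)^2)
  k <- k / sum(k)
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- matrix(0, n, n)
  inb <- abs(d) <= r
  K[inb] <- k[d[inb] + r + 1L]
  K
}

# Weighted (masked) Gaussian smoothing as a ratio of plain convolutions
# conv(w*r)/conv(w); zero total weight in a neighborhood yields NA there.
gauss_smooth2d_weighted <- function(r, w, sigma_px, truncation = 4) {
  sigma_px <- rep(sigma_px, length.out = 2L)
  K1 <- gauss_band_matrix(nrow(r), sigma_px[1], truncation)
  K2 <- gauss_band_matrix(ncol(r), sigma_px[2], truncation)
  num <- K1 %*% (w * r) %*% t(K2)
  den <- K1 %*% w %*% t(K2)
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out
}

# Separable Gaussian smoothing of a 3-D array, sigma in voxels per axis,
# edge-renormalized.
gauss_smooth3d <- function(arr, sigma_px) {
  sigma_px <- rep(sigma_px, length.out = 3L)
  d <- dim(arr)
  Ks <- lapply(1:3, function(a) gauss_conv_matrix(d[a], sigma_px[a]))
  # axis 1
  arr <- array(Ks[[1]] %*% matrix(arr, d[1]), d)
  # axis 2
  arr <- aperm(arr, c(2, 1, 3))
  arr <- array(Ks[[2]] %*% matrix(arr, d[2]), d[c(2, 1, 3)])
  arr <- aperm(arr, c(2, 1, 3))
  # axis 3
  arr <- aperm(arr, c(3, 1, 2))
  arr <- array(Ks[[3]] %*% matrix(arr, d[3]), d[c(3, 1, 2)])
  aperm(arr, c(2, 3, 1))
}

# moving-average smoothing of a numeric series (edge-truncated window)
smooth_series <- function(x, window = 5L) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - half):min(n, i + half)
    mean(x[j])
  }, numeric(1))
}

# largest connected component / connectivity of a logical 3-D array
# (6-connectivity), small and loop-free enough for phantom-sized arrays.
connected_components3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ijk <- arrayInd(cur, d)
      for (axis in 1:3) for (s in c(-1L, 1L)) {
        nb <- ijk
        nb[, axis] <- nb[, axis] + s
        ok <- nb[, axis] >= 1L & nb[, axis] <= d[axis]
        if (!any(ok)) next
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) +
          d[1] * d[2] * (nb[ok, 3] - 1L)
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}
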