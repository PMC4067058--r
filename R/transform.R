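#' Rigid (6-DOF) world-space transform
#'
#' Represents `p -> R p + t` with an orthonormal rotation `R` (det = +1)
#' and a translation `t` in mm.  Used for the per-slice motion and the
#' stack poses.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!is_orthonormal(rotation) || det(rotation) < 0)
    stop("'rotation' must be a proper rotation matrix")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rigid transform from Euler angles
#'
#' Angle convention: `R = Rz(rz) %*% Ry(ry) %*% Rx(rx)` (extrinsic
#' x-then-y-then-z), angles in degrees.  This is the parameterization the
#' 6-DOF registration optimizers work in.
#'
#' @param rx,ry,rz rotations about the world x/y/z axes, degrees.
#' @param tx,ty,tz translation in mm.
#' @return A [rigid_transform()].
#' @export
euler_transform <- function(rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0) {
  rigid_transform(euler_matrix(rx, ry, rz), c(tx, ty, tz))
}

euler_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Recover Euler angles and translation from a rigid transform
#'
#' Inverse of [euler_transform()] (Rz Ry Rx convention, degrees).  At
#' gimbal lock (|ry| = 90 deg) the rx/rz split is not unique; rx is set
#' to 0.
#'
#' @param tf a [rigid_transform()].
#' @return Named numeric vector `c(rx, ry, rz, tx, ty, tz)`.
#' @export
transform_params <- function(tf) {
  R <- tf$R
  sy <- -R[3, 1]
  if (abs(sy) < 1 - 1e-12) {
    ry <- asin(sy)
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    ry <- asin(max(-1, min(1, sy)))
    rx <- 0
    rz <- atan2(-R[1, 2], R[2, 2])
  }
  ang <- c(rx = rx, ry = ry, rz = rz) * 180 / pi
  c(ang, tx = tf$t[1], ty = tf$t[2], tz = tf$t[3])
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first: `(a o b)(p) = a(b(p))`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composed [rigid_transform()].
#' @export
compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert <- function(tf) {
  Rt <- t(tf$R)
  rigid_transform(Rt, -as.numeric(Rt %*% tf$t))
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param p length-3 vector or n x 3 matrix of world points (mm).
#' @return Transformed points, same shape as `p`.
#' @export
apply_transform <- function(tf, p) {
  pts <- to_points(p)
  out <- pts %*% t(tf$R)
  out <- sweep(out, 2L, tf$t, `+`)
  shape_like(out, p)
}

#' @export
print.rigid_transform <- function(x, ...) {
  pr <- transform_params(x)
  cat(sprintf("rigid_transform: rot (%.3f, %.3f, %.3f) deg, trans (%.3f, %.3f, %.3f) mm\n",
              pr[1], pr[2], pr[3], pr[4], pr[5], pr[6]))
  invisible(x)
}

identity_transform <- function() rigid_transform()

is_identity_transform <- function(tf, tol = 1e-12) {
  max(abs(tf$R - diag(3))) < tol && max(abs(tf$t)) < tol
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param tf a [rigid_transform()].
#' @return 4x4 matrix acting on homogeneous column vectors.
#' @export
as_matrix4 <- function(tf) {
  m <- diag(4)
  m[1:3, 1:3] <- tf$R
  m[1:3, 4] <- tf$t
  m
}

#' Rigid transform from a homogeneous 4x4 matrix
#' @param m 4x4 homogeneous matrix with a rotation upper-left block.
#' @return A [rigid_transform()].
#' @export
from_matrix4 <- function(m) rigid_transform(m[1:3, 1:3], m[1:3, 4])
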