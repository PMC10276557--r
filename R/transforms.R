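#' Rigid transform
#'
#' A rigid-body transform in 3D: `x_world = rotation %*% x + translation`.
#' Lengths are millimetres throughout the package.
#'
#' @param rotation 3x3 orthonormal rotation matrix, determinant +1.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t <- rigid_transform(diag(3), c(1, 2, 3))
#' apply_transform(t, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", format(round(x$translation, 4)), "\n")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points
#' @param t A `rigid_transform`.
#' @param pts numeric length-3 vector or an n x 3 matrix of points (mm).
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(t, pts) {
  if (is.null(dim(pts))) {
    as.numeric(t$rotation %*% pts) + t$translation
  } else {
    sweep(pts %*% t(t$rotation), 2, t$translation, "+")
  }
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

wrap_deg <- function(d) {
  w <- (d + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Six-degree-of-freedom pose
#'
#' The six design variables of the registration search: translations
#' `x, y, z` in mm and rotations `alpha, beta, gamma` in degrees. The
#' rotation is built from intrinsic rotations applied in x, then y, then z
#' order about the model's own axes (`R = Rx(alpha) Ry(beta) Rz(gamma)`);
#' this optimizer parameterization is distinct from the z-x-y Cardan
#' sequence used for reporting joint angles.
#'
#' @param x,y,z translations (mm).
#' @param alpha,beta,gamma rotations (degrees), wrapped to (-180, 180].
#' @return An object of class `pose6`.
#' @examples
#' pose_to_transform(pose6(1, 2, 3, 0, 0, 0))
#' @export
pose6 <- function(x = 0, y = 0, z = 0, alpha = 0, beta = 0, gamma = 0) {
  structure(list(x = x, y = y, z = z,
                 alpha = wrap_deg(alpha), beta = wrap_deg(beta),
                 gamma = wrap_deg(gamma)),
            class = "pose6")
}

#' @export
print.pose6 <- function(x, ...) {
  cat(sprintf(
    "pose6: t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
    x$x, x$y, x$z, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Convert a pose to a numeric vector and back
#' @param pose A `pose6`.
#' @return `pose_to_vec`: numeric length-6 `(x, y, z, alpha, beta, gamma)`.
#' @export
pose_to_vec <- function(pose) {
  c(pose$x, pose$y, pose$z, pose$alpha, pose$beta, pose$gamma)
}

#' @param v numeric length-6 `(x, y, z, alpha, beta, gamma)`.
#' @return `vec_to_pose`: a `pose6`.
#' @rdname pose_to_vec
#' @export
vec_to_pose <- function(v) {
  pose6(v[1], v[2], v[3], v[4], v[5], v[6])
}

#' Convert a 6-DOF pose to a rigid transform
#'
#' @param pose A `pose6`.
#' @return A `rigid_transform` with `R = Rx(alpha) Ry(beta) Rz(gamma)` and
#'   translation `(x, y, z)`.
#' @export
pose_to_transform <- function(pose) {
  R <- rot_x(deg2rad(pose$alpha)) %*% rot_y(deg2rad(pose$beta)) %*%
    rot_z(deg2rad(pose$gamma))
  rigid_transform(R, c(pose$x, pose$y, pose$z))
}

#' Convert a rigid transform to a 6-DOF pose
#'
#' Inverse of [pose_to_transform()]; valid away from the parameterization's
#' gimbal lock at `|beta| = 90` degrees.
#'
#' @param t A `rigid_transform`.
#' @return A `pose6`.
#' @export
transform_to_pose <- function(t) {
  R <- t$rotation
  # R = Rx(a) Ry(b) Rz(c): R[1,3] = sin(b)
  sb <- max(-1, min(1, R[1, 3]))
  if (abs(abs(sb) - 1) < 1e-9)
    stop("gimbal lock: |beta| = 90 degrees (y axis degenerate)")
  b <- asin(sb)
  a <- atan2(-R[2, 3], R[3, 3])
  cc <- atan2(-R[1, 2], R[1, 1])
  pose6(t$translation[1], t$translation[2], t$translation[3],
        rad2deg(a), rad2deg(b), rad2deg(cc))
}

#' z-x-y Cardan decomposition of a rotation
#'
#' Decomposes a rotation as `R = Rz(theta_z) Rx(theta_x) Ry(theta_y)`, the
#' Cardan sequence used for clinical joint angles: for a knee expressed as
#' the tibial pose in the femoral anatomical frame the three angles are
#' flexion/extension (z), adduction/abduction (x) and internal/external
#' rotation (y).
#'
#' @param t A `rigid_transform` (only the rotation is used).
#' @return Numeric length-3 vector `c(z, x, y)` in degrees.
#' @export
transform_to_cardan_zxy <- function(t) {
  R <- t$rotation
  sx <- max(-1, min(1, R[3, 2]))
  if (abs(abs(sx) - 1) < 1e-9)
    stop("gimbal lock: |x rotation| = 90 degrees (x axis degenerate)")
  x <- asin(sx)
  z <- atan2(-R[1, 2], R[2, 2])
  y <- atan2(-R[3, 1], R[3, 3])
  rad2deg(c(z, x, y))
}

#' Compose a rotation from z-x-y Cardan angles
#'
#' @param z,x,y angles in degrees (applied as `Rz Rx Ry`).
#' @return A `rigid_transform` with zero translation.
#' @export
cardan_zxy_to_transform <- function(z, x, y) {
  rigid_transform(rot_z(deg2rad(z)) %*% rot_x(deg2rad(x)) %*%
                    rot_y(deg2rad(y)), c(0, 0, 0))
}
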