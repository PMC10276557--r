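#' Perspective projection model of one X-ray unit
#'
#' Each fluoroscopic unit is modeled as an ideal perspective projection of a
#' point source of X-rays onto a planar detector. The detector is spanned by
#' two orthonormal axes; `detector_origin` is the 3D position of pixel
#' (0, 0)'s center. Pixel indexing is 0-based with pixel centers at integer
#' coordinates, `u` rightward and `v` downward in the image.
#'
#' @param source 3D position of the X-ray point source (mm).
#' @param detector_origin 3D position of pixel (0, 0) (mm).
#' @param u_axis,v_axis orthonormal 3-vectors spanning the detector plane.
#' @param pixel_spacing mm/pixel, length 2 `(u, v)` (a scalar is recycled).
#' @param resolution pixels, length 2 `(n_u, n_v)` (a scalar is recycled).
#' @return An object of class `projection_model`. The `principal_point`
#'   element holds the pixel coordinates of the foot of the perpendicular
#'   from the source onto the detector plane.
#' @export
projection_model <- function(source, detector_origin, u_axis, v_axis,
                             pixel_spacing, resolution) {
  source <- as.numeric(source); detector_origin <- as.numeric(detector_origin)
  u_axis <- as.numeric(u_axis); v_axis <- as.numeric(v_axis)
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2)
  resolution <- rep(as.integer(resolution), length.out = 2)
  stopifnot(length(source) == 3, length(detector_origin) == 3)
  if (abs(sum(u_axis^2) - 1) > 1e-9 || abs(sum(v_axis^2) - 1) > 1e-9)
    stop("u_axis and v_axis must be unit vectors")
  if (abs(sum(u_axis * v_axis)) > 1e-9)
    stop("u_axis and v_axis must be orthogonal")
  if (any(pixel_spacing <= 0) || any(resolution <= 0))
    stop("pixel_spacing and resolution must be positive")
  n <- cross3(u_axis, v_axis)
  d <- sum((source - detector_origin) * n)
  if (abs(d) < 1e-9) stop("source must not lie on the detector plane")
  foot <- source - d * n
  pp <- c(sum((foot - detector_origin) * u_axis) / pixel_spacing[1],
          sum((foot - detector_origin) * v_axis) / pixel_spacing[2])
  structure(list(source = source, detector_origin = detector_origin,
                 u_axis = u_axis, v_axis = v_axis,
                 pixel_spacing = pixel_spacing, resolution = resolution,
                 principal_point = pp, sdd = abs(d), normal = n),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf(
    "projection_model: %dx%d px, %.3fx%.3f mm/px, source-detector %.1f mm\n",
    x$resolution[1], x$resolution[2], x$pixel_spacing[1], x$pixel_spacing[2],
    x$sdd))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project 3D points onto the detector
#'
#' Intersects the ray from the source through each point with the detector
#' plane and returns 0-based pixel coordinates.
#'
#' @param model A `projection_model`.
#' @param p length-3 point or n x 3 matrix of points (mm).
#' @return Pixel coordinates `(u, v)`: length-2 vector or n x 2 matrix.
#' @export
project_point <- function(model, p) {
  single <- is.null(dim(p))
  P <- if (single) matrix(p, 1, 3) else as.matrix(p)
  dirs <- sweep(P, 2, model$source, "-")
  denom <- dirs %*% model$normal
  if (any(abs(denom) < 1e-12))
    stop("ray parallel to the detector plane")
  num <- sum((model$detector_origin - model$source) * model$normal)
  tt <- num / denom
  if (any(tt <= 0))
    stop("point projects behind the source (no detector intersection)")
  hit <- sweep(dirs * as.numeric(tt), 2, model$source, "+")
  rel <- sweep(hit, 2, model$detector_origin, "-")
  uv <- cbind(rel %*% model$u_axis / model$pixel_spacing[1],
              rel %*% model$v_axis / model$pixel_spacing[2])
  colnames(uv) <- c("u", "v")
  if (single) c(uv) else uv
}

#' Back-project a pixel to a 3D ray
#'
#' @param model A `projection_model`.
#' @param uv pixel coordinates `(u, v)`, 0-based.
#' @return List with `origin` (the source) and unit `direction` toward the
#'   detector pixel.
#' @export
pixel_ray <- function(model, uv) {
  pw <- model$detector_origin + uv[1] * model$pixel_spacing[1] * model$u_axis +
    uv[2] * model$pixel_spacing[2] * model$v_axis
  d <- pw - model$source
  list(origin = model$source, direction = d / sqrt(sum(d^2)))
}

#' Least-squares rigid fit between corresponding point sets
#'
#' Kabsch/Procrustes fit of the rigid transform (no scaling) minimizing
#' `sum || R src_i + t - dst_i ||^2`, used to co-register lead-marker clouds
#' between static image pairs.
#'
#' @param src,dst n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @return A `rigid_transform` with attribute `rms` (residual RMS, mm).
#' @export
rigid_point_fit <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3 || nrow(src) != nrow(dst))
    stop("need >= 3 corresponding point pairs")
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  sv <- svd(crossprod(A, B))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) point configuration")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t <- cd - as.numeric(R %*% cs)
  fit <- rigid_transform(R, t)
  res <- apply_transform(fit, src) - dst
  attr(fit, "rms") <- sqrt(mean(rowSums(res^2)))
  fit
}

#' Radio-stereometric triangulation of a marker
#'
#' Recovers a marker's 3D position from its pixel coordinates in the two
#' calibrated views as the closed-form midpoint of the common perpendicular
#' of the two back-projected rays.
#'
#' @param obs list of two pixel coordinate pairs `(u, v)`, one per plane.
#' @param models list of two `projection_model`s.
#' @return List with `point` (mm) and `residual` (half the minimal inter-ray
#'   distance, mm).
#' @export
triangulate_rsa <- function(obs, models) {
  stopifnot(length(obs) == 2, length(models) == 2)
  r1 <- pixel_ray(models[[1]], obs[[1]])
  r2 <- pixel_ray(models[[2]], obs[[2]])
  d1 <- r1$direction; d2 <- r2$direction
  cosang <- abs(sum(d1 * d2))
  if (cosang > cos(deg2rad(1)))
    stop("rays nearly parallel (angle < 1 degree); triangulation unstable")
  w0 <- r1$origin - r2$origin
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  den <- a * cc - b * b
  s <- (b * e - cc * d) / den
  t <- (a * e - b * d) / den
  p1 <- r1$origin + s * d1
  p2 <- r2$origin + t * d2
  list(point = (p1 + p2) / 2,
       residual = sqrt(sum((p1 - p2)^2)) / 2)
}
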