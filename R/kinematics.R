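#' Anatomical coordinate system (ACS)
#'
#' Bone-fixed frame with the positive x-axis directed anteriorly, positive
#' y-axis superiorly and positive z-axis to the right.
#'
#' @param origin length-3 origin (mm).
#' @param axes 3x3 right-handed orthonormal matrix whose columns are the
#'   x, y and z axes expressed in model coordinates.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, axes) {
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9 || det(axes) < 0)
    stop("axes must be right-handed orthonormal")
  structure(list(origin = as.numeric(origin), axes = axes),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame: origin", format(round(x$origin, 2)), "mm\n")
  print(round(x$axes, 4))
  invisible(x)
}

frame_to_transform <- function(frame) {
  rigid_transform(frame$axes, frame$origin)
}

# one third of the incident face areas per vertex (barycentric lumping)
vertex_area_weights <- function(mesh) {
  V <- mesh$vertices; f <- mesh$faces
  a <- V[f[, 2], ] - V[f[, 1], ]
  b <- V[f[, 3], ] - V[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  w <- numeric(nrow(V))
  for (c in 1:3) {
    t <- tapply(rep(area / 3, 1), f[, c], sum)
    w[as.integer(names(t))] <- w[as.integer(names(t))] + as.numeric(t)
  }
  w
}

#' Define an anatomical coordinate system from bone geometry
#'
#' Inertia-axis (PCA) decomposition of the vertex cloud: the first
#' principal axis (the long/superior axis) becomes y, the remaining axis
#' best aligned with the hinted medial-lateral direction becomes z, and
#' x = y cross z completes the right-handed frame. Axis signs are
#' disambiguated by the orientation hint. The origin is the centroid of
#' the articular region: the most extreme 15% of vertices along the
#' superior axis (distal end for the femur, proximal end for the tibia).
#'
#' @param mesh a `surface_mesh` in roughly anatomical orientation, or any
#'   orientation if `hint` supplies the approximate axes.
#' @param bone `"femur"` or `"tibia"`.
#' @param hint 3x3 rotation whose columns approximate the anatomical
#'   x (anterior), y (superior), z (right) directions (default identity).
#' @param articular_frac fraction of vertices defining the articular
#'   region.
#' @return An `anatomical_frame`.
#' @export
define_acs <- function(mesh, bone = c("femur", "tibia"), hint = diag(3),
                       articular_frac = 0.15) {
  bone <- match.arg(bone)
  V <- mesh$vertices
  # area-weighted vertex covariance: independent of surface sampling density
  w <- vertex_area_weights(mesh)
  ctr <- colSums(V * w) / sum(w)
  Vc <- sweep(V, 2, ctr)
  eg <- eigen(crossprod(Vc * w, Vc) / sum(w), symmetric = TRUE)
  ev <- eg$values
  if ((ev[1] - ev[2]) / ev[1] < 0.02 && (ev[2] - ev[3]) / ev[1] < 0.02)
    stop("degenerate geometry: no distinguishable principal axes")
  if ((ev[1] - ev[2]) / ev[1] < 1e-6)
    stop("degenerate geometry: leading axes indistinct")
  yax <- eg$vectors[, 1]
  if (sum(yax * hint[, 2]) < 0) yax <- -yax
  # remaining principal axis most aligned with the hinted z (right)
  cand <- eg$vectors[, 2:3, drop = FALSE]
  zi <- which.max(abs(crossprod(cand, hint[, 3])))
  zax <- cand[, zi]
  if (sum(zax * hint[, 3]) < 0) zax <- -zax
  xax <- cross3(yax, zax)
  xax <- xax / sqrt(sum(xax^2))
  zax <- cross3(xax, yax)
  axes <- cbind(xax, yax, zax)
  h <- V %*% yax
  q <- if (bone == "femur") {
    stats::quantile(h, articular_frac)
  } else {
    stats::quantile(h, 1 - articular_frac)
  }
  sel <- if (bone == "femur") h <= q else h >= q
  origin <- colMeans(V[sel, , drop = FALSE])
  anatomical_frame(origin, axes)
}

#' Transfer an ACS from a CT-based model to an SSM-reconstructed model
#'
#' Co-registers the CT-based mesh onto the reconstructed mesh with rigid
#' ICP and carries the CT model's anatomical frame through the fitted
#' transform, so both models share one consistent coordinate-system
#' definition.
#'
#' @param ct_mesh `surface_mesh` carrying the frame.
#' @param ct_frame the `anatomical_frame` defined on `ct_mesh`.
#' @param ssm_mesh target `surface_mesh`.
#' @return The transferred `anatomical_frame` on `ssm_mesh`.
#' @export
transfer_acs <- function(ct_mesh, ct_frame, ssm_mesh) {
  tr <- icp_rigid(ct_mesh, ssm_mesh)
  anatomical_frame(apply_transform(tr, ct_frame$origin),
                   tr$rotation %*% ct_frame$axes)
}

#' Joint pose of the tibia in the femoral anatomical frame
#'
#' The knee kinematics are the relative transform of the tibial ACS in the
#' femoral ACS: rotations decomposed with the z-x-y Cardan sequence into
#' flexion/extension (z), adduction/abduction (x) and internal/external
#' rotation (y); translations are the tibial origin offset expressed in the
#' femoral ACS (medial/lateral along z, anterior/posterior along x,
#' proximal/distal along y).
#'
#' @param femur_pose,tibia_pose `pose6` (or `rigid_transform`) of each bone
#'   in the common laboratory frame.
#' @param femur_frame,tibia_frame each bone's `anatomical_frame` in model
#'   coordinates.
#' @return A one-row data frame of class `joint_pose` with the six
#'   components (deg, mm).
#' @export
joint_pose <- function(femur_pose, femur_frame, tibia_pose, tibia_frame) {
  as_tr <- function(p) if (inherits(p, "pose6")) pose_to_transform(p) else p
  Tf <- compose_transforms(as_tr(femur_pose), frame_to_transform(femur_frame))
  Tt <- compose_transforms(as_tr(tibia_pose), frame_to_transform(tibia_frame))
  rel <- compose_transforms(invert_transform(Tf), Tt)
  ang <- transform_to_cardan_zxy(rel)
  t <- rel$translation
  structure(data.frame(flexion_extension = ang[1],
                       adduction_abduction = ang[2],
                       internal_external = ang[3],
                       medial_lateral = t[3],
                       anterior_posterior = t[1],
                       proximal_distal = t[2]),
            class = c("joint_pose", "data.frame"))
}

#' Joint-pose series from per-frame bone poses
#'
#' @param femur_poses,tibia_poses equal-length lists of per-frame poses.
#' @param femur_frame,tibia_frame anatomical frames (model coordinates).
#' @param times optional per-frame times (s).
#' @return Data frame with `time` and the six kinematic components, one
#'   row per frame.
#' @export
joint_pose_series <- function(femur_poses, femur_frame, tibia_poses,
                              tibia_frame, times = NULL) {
  stopifnot(length(femur_poses) == length(tibia_poses))
  rows <- lapply(seq_along(femur_poses), function(i)
    joint_pose(femur_poses[[i]], femur_frame, tibia_poses[[i]], tibia_frame))
  out <- do.call(rbind, rows)
  out$time <- if (is.null(times)) seq_along(femur_poses) else times
  out[, c("time", setdiff(names(out), "time"))]
}
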