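#' Point-to-surface distance
#'
#' Shortest Euclidean distance from each query point to the triangulated
#' surface (exact point-to-triangle, not vertex-only), the error measure
#' underlying RMSe and mTRE.
#'
#' @param p length-3 point or n x 3 matrix (mm).
#' @param surface a `surface_mesh`.
#' @param vertex_only approximate using vertex distances only (off by
#'   default; some surface-based evaluation protocols use it).
#' @return Distance(s) in mm.
#' @export
point_to_surface_distance <- function(p, surface, vertex_only = FALSE) {
  if (nrow(surface$faces) == 0) stop("empty mesh")
  P <- if (is.null(dim(p))) matrix(p, 1, 3) else as.matrix(p)
  if (vertex_only) {
    nn <- nearest_vertices(P, surface$vertices)
    d <- sqrt(rowSums((P - surface$vertices[nn, , drop = FALSE])^2))
  } else {
    d <- cpp_closest_on_mesh(P, surface$vertices, surface$faces)$distance
  }
  if (is.null(dim(p))) d[1] else d
}

#' Shape reconstruction error (RMSe)
#'
#' Root-mean-square of the point-to-surface distances from the vertices of
#' the evaluated (e.g. SSM-reconstructed) model to the reference (e.g.
#' CT-reconstructed) surface, after rigid ICP alignment of the two models.
#'
#' @param eval_mesh,ref_mesh `surface_mesh` objects.
#' @param align rigidly align `eval_mesh` to `ref_mesh` first (default).
#' @return RMSe in mm, with attribute `distances` (per-vertex).
#' @export
shape_rmse <- function(eval_mesh, ref_mesh, align = TRUE) {
  m <- eval_mesh
  if (align) m <- transform_mesh(m, icp_rigid(eval_mesh, ref_mesh))
  d <- point_to_surface_distance(m$vertices, ref_mesh)
  structure(sqrt(mean(d^2)), distances = d)
}

#' Per-frame mean target registration error series
#'
#' For each frame, the evaluated model is placed at its registered pose and
#' the reference surface at the ground-truth pose; mTRE is the mean
#' point-to-surface distance over all evaluated-model vertices. The series
#' is summarized by its mean (mmTRE), peak (pmTRE) and per-frame success
#' flags (mTRE below the success threshold, default 1.5 mm).
#'
#' @param registered_poses,truth_poses equal-length lists of `pose6` (or
#'   `rigid_transform`).
#' @param eval_mesh mesh evaluated at the registered poses (vertices used).
#' @param ref_surface reference surface placed at the truth poses.
#' @param threshold registration-success threshold (mm).
#' @return An object of class `error_series`: data frame `frames` with
#'   columns `frame`, `mtre`, `success`, plus elements `mmtre`, `pmtre`,
#'   `threshold`.
#' @export
mtre_series <- function(registered_poses, truth_poses, eval_mesh,
                        ref_surface, threshold = 1.5) {
  if (length(registered_poses) != length(truth_poses))
    stop("pose series must have equal length")
  as_tr <- function(p) if (inherits(p, "pose6")) pose_to_transform(p) else p
  mtre <- vapply(seq_along(registered_poses), function(i) {
    tr_reg <- as_tr(registered_poses[[i]])
    tr_tru <- as_tr(truth_poses[[i]])
    pts <- apply_transform(tr_reg, eval_mesh$vertices)
    ref <- transform_mesh(ref_surface, tr_tru)
    mean(point_to_surface_distance(pts, ref))
  }, numeric(1))
  structure(list(frames = data.frame(frame = seq_along(mtre), mtre = mtre,
                                     success = mtre < threshold),
                 mmtre = mean(mtre), pmtre = max(mtre),
                 threshold = threshold),
            class = "error_series")
}

#' @export
print.error_series <- function(x, ...) {
  cat(sprintf(
    "error_series: %d frames, mmTRE %.3f mm, pmTRE %.3f mm, %d/%d successful (< %.2f mm)\n",
    nrow(x$frames), x$mmtre, x$pmtre, sum(x$frames$success), nrow(x$frames),
    x$threshold))
  invisible(x)
}

#' Mean and peak absolute kinematic differences (MAD / PAD)
#'
#' Component-wise mean and peak absolute differences between two joint-pose
#' series over a motion cycle.
#'
#' @param series_a,series_b data frames with the six kinematic component
#'   columns (as produced by [joint_pose_series()]), equal length and time
#'   base.
#' @return A data frame with one row per component and columns `component`,
#'   `mad`, `pad`, `units`.
#' @export
kinematics_mad_pad <- function(series_a, series_b) {
  comps <- c("flexion_extension", "adduction_abduction", "internal_external",
             "medial_lateral", "anterior_posterior", "proximal_distal")
  units <- c(rep("deg", 3), rep("mm", 3))
  A <- as.data.frame(series_a); B <- as.data.frame(series_b)
  stopifnot(all(comps %in% names(A)), all(comps %in% names(B)))
  if (nrow(A) != nrow(B)) stop("series must have equal length")
  diffs <- abs(A[comps] - B[comps])
  data.frame(component = comps,
             mad = vapply(diffs, mean, numeric(1)),
             pad = vapply(diffs, max, numeric(1)),
             units = units, row.names = NULL)
}

#' Plot an mTRE series
#' @param series an `error_series`.
#' @param path optional PNG path; plots to the active device when `NULL`.
#' @return The input, invisibly.
#' @export
plot_mtre <- function(series, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  plot(series$frames$frame, series$frames$mtre, type = "l",
       xlab = "frame", ylab = "mTRE (mm)", main = "Registration error")
  graphics::abline(h = series$threshold, lty = 2)
  invisible(series)
}

#' Plot six kinematic components over time
#' @param series data frame from [joint_pose_series()] with a `time`
#'   column.
#' @param path optional PNG path.
#' @return The input, invisibly.
#' @export
plot_kinematics <- function(series, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  comps <- c("flexion_extension", "adduction_abduction", "internal_external",
             "medial_lateral", "anterior_posterior", "proximal_distal")
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (cmp in comps) {
    ylab <- if (cmp %in% comps[1:3]) "deg" else "mm"
    plot(series$time, series[[cmp]], type = "l", xlab = "time (s)",
         ylab = ylab, main = cmp)
  }
  invisible(series)
}
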