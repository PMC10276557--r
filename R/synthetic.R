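#' Procedural bone-analog mesh
#'
#' A smooth, watertight, asymmetric bone-like surface on a UV-sphere
#' topology: an elongated shaft with condyle-like lobes at the distal end
#' (femur analog) or a widened plateau at the proximal end (tibia analog).
#' The analogs are procedural rather than anatomical — their role is to
#' carry known ground truth with enough asymmetry to define an anatomical
#' frame and break silhouette ambiguities. Built-in anatomical axes equal
#' the identity (x anterior, y superior, z right); the origin is at the
#' centroid.
#'
#' @param bone `"femur"` or `"tibia"`.
#' @param length bone segment length (mm).
#' @param radius mean shaft radius (mm).
#' @param n_lat,n_lon surface resolution.
#' @return A `surface_mesh` (centered at its centroid).
#' @export
bone_analog <- function(bone = c("femur", "tibia"), length = 64, radius = 13,
                        n_lat = 14, n_lon = 20) {
  bone <- match.arg(bone)
  g <- uv_sphere_grid(n_lat, n_lon)
  phi <- g$phi; theta <- g$theta
  rho <- rep(radius, base::length(phi))
  if (bone == "femur") {
    # condyle lobes near the distal (lower, -y) end, posterior side; the
    # medial lobe is larger, as in a real distal femur
    amp <- c(8, 6)
    lobes <- c(pi - 0.8, pi + 0.8)
    for (i in 1:2)
      rho <- rho + amp[i] * exp(-((phi + 1.0)^2 / 0.18 +
                                    (angle_diff(theta, lobes[i]))^2 / 0.5))
    rho <- rho - 2.5 * exp(-(angle_diff(theta, 0))^2 / 0.6) *
      cos(phi)  # anterior flattening
    rho <- rho * (1 - 0.18 * pmax(phi, 0) / (pi / 2))  # shaft taper
  } else {
    # tibial plateau: widened proximal (+y) end, medial side larger, with a
    # posterior slope and an anterior tuberosity-like ridge lower down --
    # the asymmetries that make axial rotation observable in silhouettes
    rho <- rho + 7 * exp(-((phi - 1.0)^2 / 0.22)) *
      (1 + 0.35 * cos(2 * theta) + 0.3 * sin(theta))
    rho <- rho + 5 * exp(-(angle_diff(theta, pi))^2 / 0.5) *
      exp(-((phi - 0.5)^2 / 0.3))  # posterior slope asymmetry
    rho <- rho + 3.5 * exp(-(angle_diff(theta, 0))^2 / 0.35) *
      exp(-((phi - 0.1)^2 / 0.15))  # anterior ridge
    rho <- rho * (1 - 0.15 * pmax(-phi, 0) / (pi / 2))
  }
  v <- cbind(rho * cos(phi) * cos(theta),
             (length / 2) * sin(phi),
             1.25 * rho * cos(phi) * sin(theta))  # wider medio-laterally
  v <- sweep(v, 2, colMeans(v))
  out <- surface_mesh(v, g$faces)
  # the generator's ground-truth anatomical frame for this analog
  attr(out, "truth_frame") <- define_acs(out, bone)
  out
}

angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# k smooth displacement fields on the mesh, orthogonal to the 6 rigid-motion
# generators and mutually orthonormal (columns of a 3V x k matrix,
# interleaved x,y,z per vertex).
smooth_shape_modes <- function(mesh, k = 5) {
  V <- mesh$vertices
  n <- nrow(V)
  ctr <- colMeans(V)
  P <- sweep(V, 2, ctr)
  rad <- P / pmax(sqrt(rowSums(P^2)), 1e-9)  # outward radial directions
  s <- P[, 2] / max(abs(P[, 2]))             # normalized superior coord
  th <- atan2(P[, 3], P[, 1])
  # radial harmonics: products of axial polynomials and angular waves give
  # a hierarchy of smooth, increasingly local deformation fields
  axial <- list(function(s) 1 + 0 * s, function(s) s, function(s) s^2,
                function(s) sin(pi * s), function(s) cos(pi * s))
  angular <- list(function(t) 1 + 0 * t, function(t) cos(t),
                  function(t) sin(t), function(t) cos(2 * t),
                  function(t) sin(2 * t), function(t) cos(3 * t),
                  function(t) sin(3 * t))
  basis <- list(function() cbind(0 * s, s^2, 0 * s),  # nonlinear elongation
                function() rad * sin(th + s * pi))    # helical surface wave
  for (a in axial) for (g in angular)
    basis[[length(basis) + 1]] <- local({
      a0 <- a; g0 <- g
      function() rad * a0(s) * g0(th)
    })
  # lead with the global fields (inflation, taper, AP bulge, ovality, ...)
  ord <- c(3, 4, 5, 8, 10, 6, 12, 1, 2, seq_along(basis))
  basis <- basis[unique(ord)]
  k <- min(k, length(basis))
  M <- vapply(seq_len(k), function(m) as.numeric(t(basis[[m]]())),
              numeric(3 * n))
  # rigid-motion generators: 3 translations + 3 linearized rotations
  tg <- vapply(1:3, function(a) as.numeric(t(outer(rep(1, n), diag(3)[a, ]))),
               numeric(3 * n))
  rg <- vapply(1:3, function(a) {
    ax <- diag(3)[a, ]
    as.numeric(t(t(vapply(seq_len(n), function(i) cross3(ax, P[i, ]),
                          numeric(3)))))
  }, numeric(3 * n))
  G <- qr.Q(qr(cbind(tg, rg)))
  M <- M - G %*% crossprod(G, M)
  qr.Q(qr(M))[, seq_len(k), drop = FALSE]
}

#' Generate a corresponded synthetic bone-shape population
#'
#' Deforms a procedural bone analog by `k` known smooth, mutually
#' orthonormal displacement modes (orthogonal to all rigid motions) with
#' seeded Gaussian weights, emulating a training population of corresponded
#' CT-derived shapes with a known generating subspace. The default n = 60
#' mirrors a realistic training-set size.
#'
#' @param n population size (>= 3).
#' @param bone `"femur"` or `"tibia"`.
#' @param k number of generating modes.
#' @param mode_sd per-mode weight standard deviations (mm).
#' @param vertex_noise_sd SD (mm) of an additional per-shape iid vertex
#'   residual, emulating the full eigen-spectrum of real CT populations
#'   (0 keeps the population exactly rank `k`).
#' @param seed RNG seed.
#' @param ... passed to [bone_analog()].
#' @return List with `training` (a `training_set`), `base` (the base
#'   mesh), `modes` (3V x k orthonormal generating modes) and `weights`
#'   (n x k generating weights).
#' @export
generate_bone_population <- function(n = 60, bone = "femur", k = 5,
                                     mode_sd = NULL,
                                     vertex_noise_sd = 0, seed = 1, ...) {
  stopifnot(n >= 3)
  if (!is.null(seed)) set.seed(seed)
  base <- bone_analog(bone, ...)
  modes <- smooth_shape_modes(base, k)
  k <- ncol(modes)
  if (is.null(mode_sd))  # decaying spectrum, ~15% per mode beyond the fifth
    mode_sd <- c(2, 1.5, 1.2, 0.9, 0.7 * 0.85^(0:30))
  mode_sd <- mode_sd[seq_len(k)]
  W <- matrix(rnorm(n * k), n, k) %*% diag(mode_sd, k)
  v0 <- as.numeric(t(base$vertices))
  shapes <- lapply(seq_len(n), function(i) {
    v <- v0 + as.numeric(modes %*% W[i, ])
    if (vertex_noise_sd > 0)
      v <- v + rnorm(length(v), 0, vertex_noise_sd)
    surface_mesh(matrix(v, ncol = 3, byrow = TRUE), base$faces)
  })
  list(training = training_set(shapes), base = base, modes = modes,
       weights = W)
}

#' Default synthetic scene configuration
#'
#' Orthogonal bi-plane geometry about the isocenter (source-isocenter
#' 500 mm, source-detector 1000 mm), with a constant 320 mm detector field
#' of view regardless of resolution. The clinical-fidelity resolution is
#' 512 with 0.625 mm pixels; the default 128 keeps desk-scale runtimes.
#'
#' @param resolution detector resolution (pixels per axis).
#' @param voxel_spacing truth-volume voxel spacing (mm).
#' @param flexion_amplitude peak knee flexion (deg).
#' @param period motion period (s).
#' @param knee_gap articular gap between the bone analogs (mm).
#' @param noise_sd additive image noise SD (8-bit gray levels).
#' @param n_markers lead markers placed around the joint.
#' @return A named list of scene parameters.
#' @export
scene_config <- function(resolution = 128, voxel_spacing = 1.0,
                         flexion_amplitude = 60, period = 2,
                         knee_gap = 14, noise_sd = 2, n_markers = 6) {
  list(resolution = resolution,
       pixel_spacing = 0.625 * 512 / resolution,
       sid = 500, sdd = 1000,
       voxel_spacing = voxel_spacing,
       flexion_amplitude = flexion_amplitude, period = period,
       knee_gap = knee_gap, noise_sd = noise_sd, n_markers = n_markers)
}

#' Build a synthetic bi-plane fluoroscopy scene with ground truth
#'
#' Places a femur and tibia analog about the isocenter of an orthogonal
#' bi-plane system, defines a smooth flexion-extension trajectory of the
#' tibia about the mediolateral knee axis, and scatters lead markers
#' around the joint. Every output is reproducible from the seed.
#'
#' @param config a [scene_config()] list.
#' @param seed RNG seed.
#' @param femur_mesh,tibia_mesh optional subject meshes (model
#'   coordinates, centered); defaults are fresh subject draws from the
#'   generating shape distribution (never training members).
#' @return An object of class `synthetic_scene`: meshes, truth volumes,
#'   `models` (projection models A and B), `trajectory(t, bone)` giving
#'   the truth `pose6`, `markers` (3D, limb frame) and the config.
#' @export
make_scene <- function(config = scene_config(), seed = 1,
                       femur_mesh = NULL, tibia_mesh = NULL) {
  set.seed(seed + 1000003)
  if (is.null(femur_mesh)) {
    pop <- generate_bone_population(n = 3, bone = "femur", seed = seed +
                                      2000003)
    femur_mesh <- pop$training$shapes[[1]]
  }
  if (is.null(tibia_mesh)) {
    pop <- generate_bone_population(n = 3, bone = "tibia", seed = seed +
                                      3000017)
    tibia_mesh <- pop$training$shapes[[1]]
  }
  res <- config$resolution
  sp <- config$pixel_spacing
  half <- (res - 1) / 2
  mk_model <- function(src_dir, u_axis, v_axis) {
    src <- config$sid * src_dir
    center <- -(config$sdd - config$sid) * src_dir
    projection_model(src, center - half * sp * u_axis - half * sp * v_axis,
                     u_axis, v_axis, sp, res)
  }
  models <- list(A = mk_model(c(1, 0, 0), c(0, 0, 1), c(0, -1, 0)),
                 B = mk_model(c(0, 0, 1), c(-1, 0, 0), c(0, -1, 0)))
  off <- mesh_half_extent(femur_mesh) + config$knee_gap / 2
  off_t <- mesh_half_extent(tibia_mesh) + config$knee_gap / 2
  femur_pos <- c(0, off, 0)
  tibia_pos <- c(0, -off_t, 0)
  amp <- config$flexion_amplitude
  period <- config$period
  trajectory <- function(t, bone = c("tibia", "femur")) {
    bone <- match.arg(bone)
    theta <- amp / 2 * (1 - cos(2 * pi * t / period))
    if (bone == "femur") {
      pose6(femur_pos[1], femur_pos[2], femur_pos[3])
    } else {
      # flexion: tibia rotates posteriorly about the ML (z) knee axis
      R <- rot_z(deg2rad(-theta))
      p <- as.numeric(R %*% tibia_pos)
      transform_to_pose(rigid_transform(R, p))
    }
  }
  markers <- cbind(runif(config$n_markers, -30, 30),
                   runif(config$n_markers, -55, 55),
                   runif(config$n_markers, 30, 45) *
                     sample(c(-1, 1), config$n_markers, replace = TRUE))
  structure(list(
    femur_mesh = femur_mesh, tibia_mesh = tibia_mesh,
    femur_volume = voxelize_mesh(femur_mesh,
                                 spacing = config$voxel_spacing),
    tibia_volume = voxelize_mesh(tibia_mesh,
                                 spacing = config$voxel_spacing),
    models = models, trajectory = trajectory, markers = markers,
    femur_pos = femur_pos, tibia_pos = tibia_pos,
    config = config, seed = seed),
    class = "synthetic_scene")
}

mesh_half_extent <- function(mesh) {
  r <- range(mesh$vertices[, 2])
  (r[2] - r[1]) / 2
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene: %dx%d px planes, %g mm voxels, flexion 0-%g deg / %g s\n",
    x$config$resolution, x$config$resolution, x$config$voxel_spacing,
    x$config$flexion_amplitude, x$config$period))
  invisible(x)
}

# render one float scene frame: both bones at their poses for time t /
# subject rotation `rot` (a rigid_transform applied on top of poses)
render_scene_view <- function(scene, model, femur_tr, tibia_tr) {
  drf <- generate_drr(scene$femur_volume, femur_tr, model)
  drt <- generate_drr(scene$tibia_volume, tibia_tr, model)
  drf$pixels + drt$pixels
}

#' Simulate static multi-view acquisitions for shape reconstruction
#'
#' Rotates the subject (both bones and markers rigidly) about the vertical
#' isocenter axis by each plate angle, renders the bi-plane pair, projects
#' the lead markers into both planes, and adds seeded Gaussian intensity
#' noise and marker jitter. Ground truth (pair transforms, standing poses)
#' is attached for validation.
#'
#' @param scene a `synthetic_scene`.
#' @param plate_angles plate rotations (deg); the clinical protocol uses
#'   positions from 0, 30, 45 and 60.
#' @param noise_sd image noise SD (gray levels); default from the scene.
#' @param marker_jitter_px marker observation jitter SD (px); the default
#'   `NULL` uses a fixed 0.3125 mm physical jitter on the detector (0.5 px
#'   at the clinical 0.625 mm/px resolution), keeping the marker-detection
#'   noise physically realistic at reduced test resolutions.
#' @param seed RNG seed.
#' @return List with `acq` (an `acquisition_set` with truth pair
#'   transforms), `marker_obs` (per pair, per plane), and `truth` (pair
#'   transforms, femur/tibia standing poses in the pair-1 frame, gain).
#' @export
simulate_static_acquisitions <- function(scene, plate_angles = c(0, 45),
                                         noise_sd = NULL,
                                         marker_jitter_px = NULL, seed = 1) {
  set.seed(seed + 4000037)
  if (is.null(noise_sd)) noise_sd <- scene$config$noise_sd
  femur_tr <- pose_to_transform(scene$trajectory(0, "femur"))
  tibia_tr <- pose_to_transform(scene$trajectory(0, "tibia"))
  gain <- NULL
  pairs <- list()
  transforms <- list()
  marker_obs <- list()
  for (k in seq_along(plate_angles)) {
    rot <- rigid_transform(rot_y(deg2rad(plate_angles[k])), c(0, 0, 0))
    ftr <- compose_transforms(rot, femur_tr)
    ttr <- compose_transforms(rot, tibia_tr)
    imgs <- list()
    obs <- list()
    for (j in 1:2) {
      m <- scene$models[[j]]
      px <- render_scene_view(scene, m, ftr, ttr)
      if (is.null(gain)) gain <- max(px) * 1.05
      rg <- radiograph(px, plane_id = c("A", "B")[j], timestamp = 0)
      rg <- quantize_8bit(rg, lo = 0, hi = gain)
      rg$pixels <- pmin(pmax(rg$pixels +
                               round(rnorm(length(rg$pixels), 0, noise_sd)),
                             0), 255)
      imgs[[j]] <- rg
      uv <- project_point(m, apply_transform(rot, scene$markers))
      jit <- if (is.null(marker_jitter_px))
        0.3125 / m$pixel_spacing[1] else marker_jitter_px
      obs[[j]] <- uv + matrix(rnorm(length(uv), 0, jit), nrow(uv), 2)
    }
    pairs[[k]] <- list(images = imgs, models = scene$models)
    transforms[[k]] <- rot
    marker_obs[[k]] <- obs
  }
  list(acq = acquisition_set(pairs, transforms),
       marker_obs = marker_obs,
       truth = list(pair_transforms = transforms,
                    femur_pose = scene$trajectory(0, "femur"),
                    tibia_pose = scene$trajectory(0, "tibia"),
                    gain = gain))
}

#' Simulate an interleaved bi-plane fluoroscopic sequence
#'
#' Renders each frame at its own timestamp from the motion trajectory
#' (true asynchrony: planes alternate with the inter-unit offset), applies
#' a fixed intensity gain, seeded Gaussian noise and 8-bit quantization,
#' and records the ground-truth pose of both bones at every frame time.
#'
#' @param scene a `synthetic_scene`.
#' @param duration sequence duration (s).
#' @param fps per-plane frame rate (default 30).
#' @param offset inter-unit time offset (s, default 1/60).
#' @param noise_sd image noise SD (gray levels); default from the scene.
#' @param seed RNG seed.
#' @return List with `sequence` (an `interleaved_sequence`), `truth`
#'   (per-frame lists of femur and tibia `pose6`), and `gain`.
#' @export
simulate_interleaved_sequence <- function(scene, duration = 2, fps = 30,
                                          offset = 1 / 60, noise_sd = NULL,
                                          seed = 1) {
  stopifnot(duration > 0)
  set.seed(seed + 5000011)
  if (is.null(noise_sd)) noise_sd <- scene$config$noise_sd
  n_per <- floor(duration * fps)
  times_A <- (seq_len(n_per) - 1) / fps
  times_B <- times_A + offset
  ts <- c(rbind(times_A, times_B))
  ids <- rep(c("A", "B"), n_per)
  gain <- NULL
  frames <- vector("list", length(ts))
  femur_truth <- vector("list", length(ts))
  tibia_truth <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    ftr <- pose_to_transform(scene$trajectory(ts[i], "femur"))
    ttr <- pose_to_transform(scene$trajectory(ts[i], "tibia"))
    px <- render_scene_view(scene, scene$models[[ids[i]]], ftr, ttr)
    if (is.null(gain)) gain <- max(px) * 1.05
    rg <- radiograph(px, plane_id = ids[i], timestamp = ts[i])
    rg <- quantize_8bit(rg, lo = 0, hi = gain)
    rg$pixels <- pmin(pmax(rg$pixels +
                             round(rnorm(length(rg$pixels), 0, noise_sd)),
                           0), 255)
    frames[[i]] <- rg
    femur_truth[[i]] <- scene$trajectory(ts[i], "femur")
    tibia_truth[[i]] <- scene$trajectory(ts[i], "tibia")
  }
  list(sequence = interleaved_sequence(frames, fps, offset),
       truth = list(femur = femur_truth, tibia = tibia_truth),
       gain = gain)
}
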