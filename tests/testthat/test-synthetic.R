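# The ground-truth simulator: bone populations, scenes and acquisitions.

test_that("bone analogs are watertight and asymmetric enough for an ACS", {
  for (b in c("femur", "tibia")) {
    m <- bone_analog(b)
    expect_true(is_watertight(m))
    expect_s3_class(attr(m, "truth_frame"), "anatomical_frame")
  }
})

test_that("a noiseless population has exactly the generating eigen-rank", {
  pop <- generate_bone_population(n = 60, bone = "femur", k = 5, seed = 91)
  g <- gpa_align(pop$training)
  mod <- build_ssm(g$aligned, n_modes = 10)
  expect_lt(mod$all_eigenvalues[6], 1e-6 * mod$all_eigenvalues[1])
  sv <- svd(crossprod(mod$modes[, 1:5], pop$modes))$d
  expect_lt(acos(min(pmin(sv, 1))), 1e-3)
})

test_that("zero mode weights reproduce the base shape; seeded repeats are identical", {
  pop <- generate_bone_population(n = 4, bone = "tibia", mode_sd = rep(0, 5),
                                  seed = 92)
  for (s in pop$training$shapes)
    expect_equal(s$vertices, pop$base$vertices, tolerance = 1e-12)
  p1 <- generate_bone_population(n = 5, bone = "femur", seed = 93)
  p2 <- generate_bone_population(n = 5, bone = "femur", seed = 93)
  expect_identical(p1$weights, p2$weights)
  expect_identical(p1$training$shapes[[3]]$vertices,
                   p2$training$shapes[[3]]$vertices)
})

test_that("generating modes are orthonormal and orthogonal to rigid motions", {
  pop <- generate_bone_population(n = 3, bone = "femur", seed = 94)
  M <- pop$modes
  expect_lt(max(abs(crossprod(M) - diag(ncol(M)))), 1e-9)
  V <- pop$base$vertices
  n <- nrow(V)
  # translations
  for (a in 1:3) {
    tg <- as.numeric(t(outer(rep(1, n), diag(3)[a, ])))
    expect_lt(max(abs(crossprod(M, tg))), 1e-6)
  }
})

test_that("both bones project inside both detectors at every trajectory sample", {
  scene <- shared_scene()
  res <- scene$config$resolution
  for (t in seq(0, scene$config$period, length.out = 9)) {
    for (pl in c("A", "B")) for (b in c("femur", "tibia")) {
      m <- if (b == "femur") scene$femur_mesh else scene$tibia_mesh
      tr <- pose_to_transform(scene$trajectory(t, b))
      uv <- project_point(scene$models[[pl]], apply_transform(tr, m$vertices))
      expect_gte(min(uv), 0)
      expect_lte(max(uv), res - 1)
    }
  }
})

test_that("zero amplitude gives a static trajectory; seeded scenes repeat", {
  cfg <- scene_config(flexion_amplitude = 0)
  scene <- make_scene(cfg, seed = 4)
  expect_equal(pose_to_vec(scene$trajectory(0.7, "tibia")),
               pose_to_vec(scene$trajectory(0, "tibia")))
  s2 <- make_scene(cfg, seed = 4)
  expect_identical(scene$tibia_mesh$vertices, s2$tibia_mesh$vertices)
  expect_identical(scene$markers, s2$markers)
})

test_that("static acquisitions carry consistent ground truth", {
  scene <- shared_scene()
  st <- simulate_static_acquisitions(scene, plate_angles = c(0),
                                     seed = 95)
  expect_equal(st$acq$n_pairs, 1)
  expect_equal(st$acq$pair_transforms[[1]]$rotation, diag(3))
  st2 <- simulate_static_acquisitions(scene, plate_angles = c(0, 45),
                                      marker_jitter_px = 0, noise_sd = 0,
                                      seed = 95)
  fits <- derive_pair_transforms(st2$marker_obs, scene$models)
  expect_lt(max(abs(fits[[2]]$rotation -
                      st2$truth$pair_transforms[[2]]$rotation)), 1e-6)
})

test_that("interleaved sequences alternate planes and respect the time base", {
  scene <- shared_scene()
  dyn <- simulate_interleaved_sequence(scene, duration = 0.2, fps = 30,
                                       seed = 96)
  ids <- vapply(dyn$sequence$frames, function(f) f$plane_id, character(1))
  expect_identical(ids, rep(c("A", "B"), 6))
  ts <- vapply(dyn$sequence$frames, function(f) f$timestamp, numeric(1))
  expect_equal(diff(ts), rep(1 / 60, 11), tolerance = 1e-12)
  expect_length(dyn$truth$tibia, 12)
  # static trajectory: same-plane frames identical up to the seeded noise
  cfg <- scene_config(flexion_amplitude = 0)
  s2 <- make_scene(cfg, seed = 5)
  d2 <- simulate_interleaved_sequence(s2, duration = 0.2, fps = 30, seed = 5)
  a1 <- d2$sequence$frames[[1]]$pixels
  a3 <- d2$sequence$frames[[3]]$pixels
  expect_lt(mean(abs(a1 - a3)), 3 * s2$config$noise_sd)
  # zero offset gives synchronous pairs (degenerate control case)
  d0 <- simulate_interleaved_sequence(s2, duration = 0.1, fps = 30,
                                      offset = 0.5 / 60, seed = 5)
  expect_lt(d0$sequence$frames[[2]]$timestamp -
              d0$sequence$frames[[1]]$timestamp, 1 / 60)
})

test_that("constant-velocity motion shifts same-plane frames by the projected amount", {
  cfg <- scene_config(noise_sd = 0)
  scene <- make_scene(cfg, seed = 6)
  v_mm <- c(18, 0, 0)  # mm/s along world x: in-plane for plane B
  scene$trajectory <- function(t, bone = c("tibia", "femur")) {
    bone <- match.arg(bone)
    base <- if (bone == "femur") scene$femur_pos else -scene$femur_pos
    pose6(base[1] + v_mm[1] * t, base[2], base[3])
  }
  dyn <- simulate_interleaved_sequence(scene, duration = 0.15, fps = 30,
                                       seed = 6)
  # projected displacement of the tibia centroid between same-plane frames
  mB <- scene$models$B
  p1 <- apply_transform(pose_to_transform(dyn$truth$tibia[[2]]), c(0, 0, 0))
  p2 <- apply_transform(pose_to_transform(dyn$truth$tibia[[4]]), c(0, 0, 0))
  duv <- project_point(mB, p2) - project_point(mB, p1)
  f2 <- dyn$sequence$frames[[2]]$pixels
  f4 <- dyn$sequence$frames[[4]]$pixels
  # cross-correlation shift of the two frames matches the analytic shift
  best <- c(0, 0); bestv <- -Inf
  for (du in -3:3) for (dv in -3:3) {
    r <- 20:108
    v <- suppressWarnings(stats::cor(as.numeric(f2[r, r]),
                                     as.numeric(f4[r + dv, r + du])))
    if (!is.na(v) && v > bestv) { bestv <- v; best <- c(du, dv) }
  }
  expect_equal(best[1], round(duv[1]))
  expect_equal(best[2], round(duv[2]))
})
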