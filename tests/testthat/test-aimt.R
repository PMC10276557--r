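# Particle-filter template tracking, frame interpolation and the AIMT loop.

test_that("interleaved sequences must alternate planes with increasing time", {
  f <- function(pl, t) radiograph(matrix(0, 4, 4), pl, t)
  expect_s3_class(interleaved_sequence(list(f("A", 0), f("B", 1 / 60),
                                            f("A", 2 / 60))),
                  "interleaved_sequence")
  expect_error(interleaved_sequence(list(f("A", 0), f("A", 1 / 60))),
               "alternate")
  expect_error(interleaved_sequence(list(f("A", 0.5), f("B", 0.1))),
               "increase")
})

test_that("template tracking recovers static, shifted and rotated frames", {
  base <- test_texture(128)
  A <- radiograph(base, "A", 0)
  reg <- c(32, 96, 32, 96)
  set.seed(81)
  st <- template_track_2d(A, A, reg, tracker_state())
  expect_lt(max(abs(st$increment[1:2])), 0.2)
  expect_lt(abs(st$increment[3]), 0.1)
  expect_equal(sum(st$state$weights), 1, tolerance = 1e-9)
  # integer shift (3, -2)
  shifted <- radiograph(rigid_resample(base, du = 3, dv = -2), "A", 1 / 30)
  si <- template_track_2d(A, shifted, reg, tracker_state())$increment
  expect_lt(max(abs(si[1:2] - c(3, -2))), 0.5)
  expect_lt(abs(si[3]), 0.2)
  # 2 degree rotation about the template center
  rotd <- radiograph(rigid_resample(base, theta_deg = 2, center = c(64, 64)),
                     "A", 1 / 30)
  ri <- template_track_2d(A, rotd, reg, tracker_state())$increment
  expect_lt(abs(ri[3] - 2), 0.3)
})

test_that("tracking a featureless region is reported as lost", {
  flat <- radiograph(matrix(0, 64, 64), "A", 0)
  expect_error(template_track_2d(flat, flat, c(16, 48, 16, 48),
                                 tracker_state()),
               "lost")
})

test_that("zero 2D increments leave the pose unchanged", {
  models <- test_biplane()
  p0 <- pose6(3, -4, 5, 10, -8, 6)
  pred <- increments_to_3d(c(0, 0, 0), c(0, 0, 0), models, p0)
  expect_equal(pose_to_vec(pred), pose_to_vec(p0), tolerance = 1e-9)
})

test_that("an in-plane translation is recovered from its projections", {
  models <- test_biplane()
  # 4 mm world translation along plane A's u axis (world z), which is pure
  # depth for plane B
  d_world <- 4 * models$A$u_axis
  p0 <- pose6()
  obj <- c(0, 0, 0)
  uv0 <- project_point(models$A, obj)
  uv1 <- project_point(models$A, obj + d_world)
  incA <- c(uv1 - uv0, 0)
  pred <- increments_to_3d(incA, c(0, 0, 0), models, p0)
  err <- sqrt(sum((c(pred$x, pred$y, pred$z) - d_world)^2))
  expect_lt(err, 0.1 * 4)
})

test_that("applying an increment and its negation returns to the start", {
  models <- test_biplane()
  p0 <- pose6(1, 2, 3, 4, 5, 6)
  fwd <- increments_to_3d(c(2, -1, 1), c(1, 3, -0.8), models, p0)
  back <- increments_to_3d(-c(2, -1, 1), -c(1, 3, -0.8), models, fwd)
  # residuals: small-angle non-commutation plus the depth-dependent change
  # of the magnification between the two applications
  expect_lt(max(abs(pose_to_vec(back) - pose_to_vec(p0))), 0.2)
})

test_that("frame interpolation reproduces static frames and halves a translation", {
  base <- test_texture(128)
  A <- radiograph(base, "A", 0)
  same <- interpolate_frame(A, radiograph(base, "A", 2 / 30))
  expect_false(attr(same, "degenerate"))
  expect_equal(same$timestamp, 1 / 30)
  psnr <- function(x, y) 10 * log10(255^2 / max(1e-12, mean((x - y)^2)))
  expect_gt(psnr(same$pixels, base), 50)
  # 4 px translation: interpolated frame matches the analytic 2 px midpoint
  moved <- radiograph(rigid_resample(base, du = 4), "A", 2 / 30)
  mid <- interpolate_frame(A, moved)
  truth <- rigid_resample(base, du = 2)
  inner <- 12:116
  expect_gt(psnr(mid$pixels[inner, inner], truth[inner, inner]), 30)
})

test_that("interpolation is time-symmetric on translating patterns", {
  base <- test_texture(128)
  A <- radiograph(base, "A", 0)
  B <- radiograph(rigid_resample(base, du = 4), "A", 2 / 30)
  m1 <- interpolate_frame(A, B)
  m2 <- interpolate_frame(B, A)
  inner <- 12:116
  mad <- mean(abs(m1$pixels[inner, inner] - m2$pixels[inner, inner]))
  expect_lt(mad, 1)
})

test_that("uncorrelated noise falls back to averaging with a flag", {
  set.seed(82)
  N1 <- radiograph(matrix(runif(4096) * 255, 64, 64), "A", 0)
  N2 <- radiograph(matrix(runif(4096) * 255, 64, 64), "A", 1 / 30)
  out <- interpolate_frame(N1, N2)
  expect_true(attr(out, "degenerate"))
  expect_equal(out$pixels, (N1$pixels + N2$pixels) / 2)
})

test_that("an empty sequence yields an empty tracking result", {
  scene <- shared_scene()
  seq0 <- structure(list(frames = list(), fps = 30, offset = 1 / 60),
                    class = "interleaved_sequence")
  res <- track_sequence(scene$tibia_volume, seq0, pose6(), scene$models)
  expect_equal(nrow(res$frames), 0)
})

test_that("a static scene is tracked to the intensity-noise floor at every frame", {
  cfg <- scene_config(flexion_amplitude = 0)
  scene <- make_scene(cfg, seed = 3)
  dyn <- simulate_interleaved_sequence(scene, duration = 10 / 60, fps = 30,
                                       seed = 3)
  res <- track_sequence(scene$femur_volume, dyn$sequence,
                        dyn$truth$femur[[1]], scene$models,
                        settings = search_settings(pop_size = 40,
                                                   generations = 12,
                                                   polish = TRUE,
                                                   pose_bounds =
                                                     rep(3, 6)),
                        seed = 83)
  # translations within 0.3 mm; rotations within 0.6 deg (the seeded
  # sigma = 2 gray-level image noise leaves a ~0.5 deg rotational noise
  # floor in the similarity at this resolution; noiseless registration is
  # exact); surface error (mTRE) stays below 0.3 mm throughout
  for (i in seq_along(res$poses)) {
    err <- abs(pose_to_vec(res$poses[[i]]) -
                 pose_to_vec(dyn$truth$femur[[i]]))
    expect_lt(max(err[1:3]), 0.3)
    expect_lt(max(err[4:6]), 0.6)
  }
  es <- mtre_series(res$poses, dyn$truth$femur, scene$femur_mesh,
                    scene$femur_mesh)
  expect_lt(es$pmtre, 0.3)
})
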