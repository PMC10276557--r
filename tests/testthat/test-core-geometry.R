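test_that("pose/transform conversions handle identity and pure translation", {
  t0 <- pose_to_transform(pose6())
  expect_equal(t0$rotation, diag(3))
  expect_equal(t0$translation, c(0, 0, 0))
  t1 <- pose_to_transform(pose6(1, 2, 3))
  expect_equal(t1$rotation, diag(3))
  expect_equal(t1$translation, c(1, 2, 3))
})

test_that("single-axis pose rotation matches the closed-form axis rotation", {
  a <- 30 * pi / 180
  expected <- matrix(c(1, 0, 0,
                       0, cos(a), sin(a),
                       0, -sin(a), cos(a)), 3, 3)
  expect_equal(pose_to_transform(pose6(alpha = 30))$rotation, expected,
               tolerance = 1e-12)
})

test_that("pose round trip is exact away from gimbal lock", {
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    p <- pose6(runif(1, -50, 50), runif(1, -50, 50), runif(1, -50, 50),
               runif(1, -179, 179), runif(1, -85, 85), runif(1, -179, 179))
    p2 <- transform_to_pose(pose_to_transform(p))
    worst <- max(worst, max(abs(pose_to_vec(p) - pose_to_vec(p2))))
  }
  expect_lt(worst, 1e-8)
  expect_error(transform_to_pose(pose_to_transform(pose6(beta = 90))),
               "gimbal")
})

test_that("z-x-y Cardan decomposition inverts composition", {
  expect_equal(transform_to_cardan_zxy(rigid_transform()), c(0, 0, 0))
  expect_equal(transform_to_cardan_zxy(cardan_zxy_to_transform(25, 0, 0)),
               c(25, 0, 0), tolerance = 1e-10)
  expect_equal(transform_to_cardan_zxy(cardan_zxy_to_transform(10, -5, 7)),
               c(10, -5, 7), tolerance = 1e-10)
  set.seed(12)
  for (i in 1:200) {
    ang <- c(runif(1, -179, 179), runif(1, -85, 85), runif(1, -179, 179))
    tr <- cardan_zxy_to_transform(ang[1], ang[2], ang[3])
    expect_equal(transform_to_cardan_zxy(tr), ang, tolerance = 1e-8)
  }
  expect_error(transform_to_cardan_zxy(cardan_zxy_to_transform(0, 90, 0)),
               "gimbal")
})

test_that("projection sends the principal ray to the principal point", {
  m <- test_projection()
  # a point on the source-to-principal-point axis
  foot <- m$detector_origin + m$principal_point[1] * m$pixel_spacing[1] *
    m$u_axis + m$principal_point[2] * m$pixel_spacing[2] * m$v_axis
  p <- m$source + 0.4 * (foot - m$source)
  expect_equal(project_point(m, p), m$principal_point, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a point on the detector plane projects to itself", {
  m <- test_projection()
  p <- m$detector_origin + 11 * m$pixel_spacing[1] * m$u_axis +
    23 * m$pixel_spacing[2] * m$v_axis
  expect_equal(project_point(m, p), c(11, 23), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("projection matches an independent line-plane intersection", {
  set.seed(13)
  m <- test_projection()
  n <- cross3_oracle(m$u_axis, m$v_axis)
  for (i in 1:20) {
    p <- c(runif(1, -60, 60), runif(1, -60, 60), runif(1, -60, 60))
    # solve source + t (p - source) on the plane by direct algebra
    tt <- sum((m$detector_origin - m$source) * n) / sum((p - m$source) * n)
    hit <- m$source + tt * (p - m$source)
    uv <- c(sum((hit - m$detector_origin) * m$u_axis) / m$pixel_spacing[1],
            sum((hit - m$detector_origin) * m$v_axis) / m$pixel_spacing[2])
    expect_equal(project_point(m, p), uv, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("projection is invariant under common rigid motion of scene and camera", {
  set.seed(14)
  m <- test_projection()
  p <- c(20, -15, 8)
  uv0 <- project_point(m, p)
  mv <- pose_to_transform(pose6(5, -3, 9, 20, 35, -40))
  m2 <- projection_model(apply_transform(mv, m$source),
                         apply_transform(mv, m$detector_origin),
                         as.numeric(mv$rotation %*% m$u_axis),
                         as.numeric(mv$rotation %*% m$v_axis),
                         m$pixel_spacing, m$resolution)
  expect_equal(project_point(m2, apply_transform(mv, p)), uv0,
               tolerance = 1e-8)
})

test_that("rigid point fit recovers exact and noisy transforms", {
  set.seed(15)
  src <- matrix(runif(30, -40, 40), 10, 3)
  fit0 <- rigid_point_fit(src, src)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  expect_lt(attr(fit0, "rms"), 1e-9)
  tr <- pose_to_transform(pose6(4, -2, 7, 25, -40, 65))
  dst <- apply_transform(tr, src)
  fit <- rigid_point_fit(src, dst)
  expect_equal(fit$rotation, tr$rotation, tolerance = 1e-9)
  expect_equal(fit$translation, tr$translation, tolerance = 1e-9)
  # Monte-Carlo residual with isotropic noise sigma = 0.1 mm per coordinate:
  # the 3D distance RMS concentrates near sigma * sqrt(3) (minus fitted DOF)
  rms <- replicate(20, {
    noisy <- dst + matrix(rnorm(30, 0, 0.1), 10, 3)
    attr(rigid_point_fit(src, noisy), "rms")
  })
  expect_gt(mean(rms), 0.5 * 0.1 * sqrt(3))
  expect_lt(mean(rms), 1.5 * 0.1 * sqrt(3))
  # degenerate collinear configuration
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(rigid_point_fit(line, line), "collinear|degenerate")
})

test_that("RSA triangulation recovers forward-projected markers", {
  models <- test_biplane()
  set.seed(16)
  for (i in 1:10) {
    p <- c(runif(1, -50, 50), runif(1, -50, 50), runif(1, -50, 50))
    obs <- list(project_point(models$A, p), project_point(models$B, p))
    res <- triangulate_rsa(obs, models)
    expect_equal(res$point, p, tolerance = 1e-6, ignore_attr = TRUE)
    expect_lt(res$residual, 1e-6)
  }
  # isocenter of the symmetric orthogonal geometry
  iso <- triangulate_rsa(list(project_point(models$A, c(0, 0, 0)),
                              project_point(models$B, c(0, 0, 0))), models)
  expect_equal(iso$point, c(0, 0, 0), tolerance = 1e-6)
})

test_that("RSA error under pixel noise stays within the magnification bound", {
  models <- test_biplane()
  set.seed(17)
  p <- c(10, 5, -15)
  bound <- 2 * models$A$pixel_spacing[1]  # x magnification ~ sdd/sid = 2
  for (i in 1:25) {
    obs <- list(project_point(models$A, p) + rnorm(2, 0, 0.5),
                project_point(models$B, p) + rnorm(2, 0, 0.5))
    res <- triangulate_rsa(obs, models)
    expect_lt(sqrt(sum((res$point - p)^2)), bound)
  }
})

test_that("near-parallel rays are rejected", {
  mA <- test_projection()
  mB <- test_projection(dir = c(cos(0.5 * pi / 180), sin(0.5 * pi / 180), 0),
                        u_axis = c(0, 0, 1),
                        v_axis = cross3_oracle(c(cos(0.5 * pi / 180),
                                                 sin(0.5 * pi / 180), 0),
                                               c(0, 0, 1)))
  p <- c(5, 5, 5)
  expect_error(triangulate_rsa(list(project_point(mA, p),
                                    project_point(mB, p)),
                               list(mA, mB)), "parallel")
})
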