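# Correspondence, Procrustes alignment and the principal-component shape
# model.

test_that("correspondence recovers a rigidly moved copy of the reference", {
  ref <- bone_analog("femur")
  tr <- pose_to_transform(pose6(4, -6, 3, 8, -12, 10))
  target <- transform_mesh(ref, tr)
  out <- establish_correspondence(ref, target)
  expect_lt(attr(out, "mean_surface_distance"), 1e-3)
  # vertices land near their rigidly moved counterparts (true correspondence)
  expect_lt(mean(sqrt(rowSums((out$vertices - target$vertices)^2))), 0.5)
})

test_that("correspondence recovers a smooth radial deformation", {
  ref <- bone_analog("tibia")
  ctr <- colMeans(ref$vertices)
  P <- sweep(ref$vertices, 2, ctr)
  r <- sqrt(rowSums(P^2))
  # smooth radial bump, amplitude 2 mm
  amp <- 2 * exp(-((ref$vertices[, 2] - 10)^2) / 200)
  target <- surface_mesh(ref$vertices + P / r * amp, ref$faces)
  out <- establish_correspondence(ref, target)
  expect_lt(attr(out, "mean_surface_distance"), 0.3)
})

test_that("correspondence absorbs a 10% scale difference", {
  ref <- bone_analog("femur")
  target <- surface_mesh(ref$vertices * 1.1, ref$faces)
  out <- establish_correspondence(ref, target)
  expect_lt(attr(out, "mean_surface_distance"), 0.2)
})

test_that("correspondence is idempotent on its own output", {
  ref <- bone_analog("femur")
  target <- surface_mesh(ref$vertices * 1.05, ref$faces)
  out1 <- establish_correspondence(ref, target)
  out2 <- establish_correspondence(out1, target)
  expect_lt(mean(sqrt(rowSums((out2$vertices - out1$vertices)^2))), 1e-3)
})

test_that("GPA aligns rigid copies of one shape exactly", {
  base <- bone_analog("tibia", n_lat = 8, n_lon = 12)
  set.seed(21)
  shapes <- lapply(1:6, function(i)
    transform_mesh(base, pose_to_transform(random_pose())))
  g <- gpa_align(training_set(shapes))
  for (s in g$aligned$shapes)
    expect_lt(max(abs(s$vertices - g$aligned$shapes[[1]]$vertices)), 1e-5)
})

test_that("GPA mean recovers the generating mean shape", {
  pop <- generate_bone_population(n = 30, bone = "femur", seed = 31)
  # perturb each shape rigidly, then align
  set.seed(32)
  moved <- lapply(pop$training$shapes, function(s)
    transform_mesh(s, pose_to_transform(
      pose6(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5),
            runif(1, -10, 10), runif(1, -10, 10), runif(1, -10, 10)))))
  g <- gpa_align(training_set(moved))
  # the converged mean matches the generating base up to rigid pose
  fit <- icp_rigid(g$mean, pop$base)
  aligned_mean <- apply_transform(fit, g$mean$vertices)
  rmsd <- sqrt(mean(rowSums((aligned_mean - pop$base$vertices)^2)))
  expect_lt(rmsd, 0.2)
})

test_that("identical training shapes give a zero-variance model", {
  base <- bone_analog("femur", n_lat = 6, n_lon = 8)
  ts <- training_set(lapply(1:5, function(i) base))
  g <- gpa_align(ts)
  mod <- build_ssm(g$aligned, n_modes = 3)
  expect_lt(max(mod$all_eigenvalues), 1e-12)
  expect_equal(matrix(mod$mean_shape, ncol = 3, byrow = TRUE),
               sweep(base$vertices, 2, colMeans(base$vertices)),
               tolerance = 1e-9)
})

test_that("PCA recovers a known 3-mode generating subspace", {
  pop <- generate_bone_population(n = 50, bone = "tibia", k = 3,
                                  mode_sd = c(2, 1.5, 1), seed = 33)
  g <- gpa_align(pop$training)
  mod <- build_ssm(g$aligned, n_modes = 5)
  # subspace angle between leading-3 eigenspace and the generating modes
  sv <- svd(crossprod(mod$modes[, 1:3], pop$modes))$d
  max_angle <- acos(min(pmin(sv, 1)))
  expect_lt(max_angle, 1e-3)
  expect_lt(mod$all_eigenvalues[4], 1e-6 * mod$all_eigenvalues[1])
})

test_that("eigenvalues conserve the total aligned variance", {
  pop <- generate_bone_population(n = 20, bone = "femur", seed = 34,
                                  vertex_noise_sd = 0.05)
  g <- gpa_align(pop$training)
  mod <- build_ssm(g$aligned, n_modes = 19)
  X <- t(vapply(g$aligned$shapes, function(s) as.numeric(t(s$vertices)),
                numeric(3 * mod$V)))
  total <- sum(sweep(X, 2, colMeans(X))^2) / (nrow(X) - 1)
  expect_equal(sum(mod$all_eigenvalues), total, tolerance = 1e-8)
  expect_true(all(diff(mod$all_eigenvalues) <= 1e-12))
  # modes orthonormal
  expect_lt(max(abs(crossprod(mod$modes) - diag(mod$M))), 1e-8)
})

test_that("mode count beyond training size - 1 is rejected", {
  pop <- generate_bone_population(n = 5, bone = "femur", seed = 35)
  g <- gpa_align(pop$training)
  expect_error(build_ssm(g$aligned, n_modes = 5), "exceeds")
})

test_that("synthesis is linear in the coefficients", {
  pop <- generate_bone_population(n = 20, bone = "tibia", seed = 36)
  mod <- build_ssm(gpa_align(pop$training)$aligned, n_modes = 5)
  expect_equal(synthesize_shape(mod)$vertices,
               matrix(mod$mean_shape, ncol = 3, byrow = TRUE))
  w <- 2.5
  one_hot <- synthesize_shape(mod, c(0, 0, w))
  manual <- mod$mean_shape + w * mod$modes[, 3]
  expect_equal(one_hot$vertices, matrix(manual, ncol = 3, byrow = TRUE),
               tolerance = 1e-12)
  set.seed(37)
  b1 <- rnorm(5); b2 <- rnorm(5)
  s0 <- synthesize_shape(mod)$vertices
  lhs <- synthesize_shape(mod, b1 + b2)$vertices - s0
  rhs <- (synthesize_shape(mod, b1)$vertices - s0) +
    (synthesize_shape(mod, b2)$vertices - s0)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("projection onto all modes reproduces a training shape exactly", {
  pop <- generate_bone_population(n = 12, bone = "femur", seed = 38,
                                  vertex_noise_sd = 0.05)
  g <- gpa_align(pop$training)
  mod <- build_ssm(g$aligned, n_modes = 11)
  target <- g$aligned$shapes[[4]]
  b <- project_shape(mod, target)
  rec <- synthesize_shape(mod, b)
  expect_lt(max(abs(rec$vertices - target$vertices)), 1e-6)
})

test_that("shape model archive round trips losslessly", {
  pop <- generate_bone_population(n = 10, bone = "tibia", seed = 39)
  mod <- build_ssm(gpa_align(pop$training)$aligned, n_modes = 4)
  p <- file.path(tempdir(), "model.json")
  save_shape_model(mod, p)
  m2 <- load_shape_model(p)
  expect_equal(m2$mean_shape, mod$mean_shape)
  expect_equal(m2$modes, mod$modes, ignore_attr = TRUE)
  expect_equal(m2$eigenvalues, mod$eigenvalues)
  expect_identical(m2$faces, mod$faces)
})
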