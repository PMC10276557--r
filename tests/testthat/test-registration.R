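# Gradient-correlation similarity, the multi-view cost and the GA search.

test_that("gradient correlation equals the direct-summation reference", {
  set.seed(41)
  for (i in 1:25) {
    A <- matrix(runif(64, 0, 255), 8, 8)
    B <- matrix(runif(64, 0, 255), 8, 8)
    expect_equal(gradient_correlation(A, B)$f_gc, gc_bruteforce(A, B),
                 tolerance = 1e-12)
  }
})

test_that("identical images score exactly 2 and affine remaps do not change it", {
  set.seed(42)
  A <- matrix(runif(400, 0, 255), 20, 20)
  r <- gradient_correlation(A, A)
  expect_equal(r$f_gc, 2)
  expect_equal(r$horizontal, 1)
  expect_equal(r$vertical, 1)
  expect_equal(gradient_correlation(A, 3.7 * A + 42)$f_gc, 2,
               tolerance = 1e-12)
})

test_that("gradient correlation is symmetric and affine-invariant over seeded pairs", {
  set.seed(43)
  for (i in 1:100) {
    A <- matrix(runif(144, 0, 255), 12, 12)
    B <- matrix(runif(144, 0, 255), 12, 12)
    f1 <- gradient_correlation(A, B)$f_gc
    expect_equal(gradient_correlation(B, A)$f_gc, f1, tolerance = 1e-12)
    a <- runif(1, 0.1, 5); cc <- runif(1, -50, 50)
    expect_equal(gradient_correlation(a * A + cc, B)$f_gc, f1,
                 tolerance = 1e-10)
  }
})

test_that("flat images are rejected (undefined normalization)", {
  A <- matrix(5, 10, 10)
  B <- matrix(runif(100), 10, 10)
  expect_error(gradient_correlation(A, B), "variance|flat")
  expect_error(gradient_correlation(B, A), "variance|flat")
  expect_error(gradient_correlation(B, matrix(runif(64), 8, 8)),
               "dimensions")
})

test_that("multi-view cost is -2N at a self-similar render and bounded for one view", {
  scene <- shared_scene()
  truth <- scene$trajectory(0.2, "tibia")
  tr <- pose_to_transform(truth)
  drA <- generate_drr(scene$tibia_volume, tr, scene$models$A)
  drB <- generate_drr(scene$tibia_volume, tr, scene$models$B)
  views <- list(list(image = radiograph(drA$pixels), model = scene$models$A),
                list(image = radiograph(drB$pixels), model = scene$models$B))
  cost <- multiview_cost(scene$tibia_volume, truth, views)
  expect_lt(abs(as.numeric(cost) - (-4)), 1e-3)
  one <- multiview_cost(scene$tibia_volume, truth, views[1])
  expect_gte(as.numeric(one), -2)
  expect_lte(as.numeric(one), 2)
})

test_that("an out-of-plane pose perturbation raises the cost", {
  scene <- shared_scene()
  truth <- scene$trajectory(0.2, "tibia")
  tr <- pose_to_transform(truth)
  drA <- generate_drr(scene$tibia_volume, tr, scene$models$A)
  views <- list(list(image = radiograph(drA$pixels), model = scene$models$A),
                list(image = radiograph(
                  generate_drr(scene$tibia_volume, tr,
                               scene$models$B)$pixels),
                  model = scene$models$B))
  c0 <- as.numeric(multiview_cost(scene$tibia_volume, truth, views))
  # 5 mm along plane A's depth axis (x) is out-of-plane for that view
  off <- vec_to_pose(pose_to_vec(truth) + c(5, 0, 0, 0, 0, 0))
  expect_gt(as.numeric(multiview_cost(scene$tibia_volume, off, views)), c0)
})

test_that("truth pose scores no worse than seeded perturbed poses", {
  scene <- shared_scene()
  truth <- scene$trajectory(0.2, "tibia")
  tr <- pose_to_transform(truth)
  views <- lapply(c("A", "B"), function(pl)
    list(image = radiograph(generate_drr(scene$tibia_volume, tr,
                                         scene$models[[pl]])$pixels),
         model = scene$models[[pl]]))
  c0 <- as.numeric(multiview_cost(scene$tibia_volume, truth, views))
  set.seed(44)
  for (i in 1:50) {
    d <- rnorm(6)
    d <- d / max(abs(d)) * runif(1, 1, 3)  # at least 1 mm / 1 deg somewhere
    pert <- vec_to_pose(pose_to_vec(truth) + d)
    expect_gte(as.numeric(multiview_cost(scene$tibia_volume, pert, views)),
               c0)
  }
})

test_that("the GA minimizes the 6-D sphere function", {
  res <- ga_optimize(function(v) sum(v^2), rep(-10, 6), rep(10, 6),
                     search_settings(seed = 45))
  expect_lt(sqrt(sum(res$par^2)), 1e-2 * 10)
  expect_lt(res$value, 1e-2)
})

test_that("a constant cost returns an in-bounds vector at that cost", {
  res <- ga_optimize(function(v) 7.5, c(-1, -1), c(1, 1),
                     search_settings(pop_size = 10, generations = 3,
                                     seed = 46))
  expect_equal(res$value, 7.5)
  expect_true(all(res$par >= -1 & res$par <= 1))
})

test_that("seeded GA runs are bit-identical and elitism is monotone", {
  f <- function(v) sum((v - 1)^2) + sin(3 * v[1])
  s <- search_settings(pop_size = 20, generations = 10, seed = 47)
  r1 <- ga_optimize(f, c(-5, -5), c(5, 5), s)
  r2 <- ga_optimize(f, c(-5, -5), c(5, 5), s)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)
  # best-ever cost never increases along the trace
  expect_true(all(diff(r1$trace) <= 0))
  # never worse than the best initial individual (seeded init)
  r3 <- ga_optimize(f, c(-5, -5), c(5, 5), s, init = c(0, 0))
  expect_lte(r3$value, f(c(0, 0)))
})

test_that("registration refuses an initial pose outside the bounds", {
  scene <- shared_scene()
  truth <- scene$trajectory(0, "tibia")
  pair <- lapply(c("A", "B"), function(pl)
    list(image = radiograph(generate_drr(scene$tibia_volume,
                                         pose_to_transform(truth),
                                         scene$models[[pl]])$pixels),
         model = scene$models[[pl]]))
  expect_error(
    biplane_register(scene$tibia_volume, truth, pair,
                     lower = pose_to_vec(truth) + 1,
                     upper = pose_to_vec(truth) + 2),
    "outside")
})

test_that("registration from the truth stays at the truth", {
  scene <- shared_scene()
  truth <- scene$trajectory(0, "tibia")
  pair <- lapply(c("A", "B"), function(pl)
    list(image = radiograph(generate_drr(scene$tibia_volume,
                                         pose_to_transform(truth),
                                         scene$models[[pl]])$pixels),
         model = scene$models[[pl]]))
  reg <- biplane_register(scene$tibia_volume, truth, pair,
                          search_settings(pop_size = 20, generations = 5,
                                          polish = TRUE, seed = 48))
  err <- abs(pose_to_vec(reg) - pose_to_vec(truth))
  expect_lt(max(err[1:3]), 0.1)
  expect_lt(max(err[4:6]), 0.1)
})
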