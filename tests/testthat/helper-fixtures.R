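# Shared fixtures built in code: small projection geometries, textured test
# images and a cached low-resolution synthetic scene.

test_projection <- function(res = 64, sid = 500, sdd = 1000,
                            fov = 320, dir = c(1, 0, 0),
                            u_axis = c(0, 0, 1), v_axis = c(0, -1, 0)) {
  sp <- fov / res
  half <- (res - 1) / 2
  src <- sid * dir
  center <- -(sdd - sid) * dir
  projection_model(src, center - half * sp * u_axis - half * sp * v_axis,
                   u_axis, v_axis, sp, res)
}

test_biplane <- function(res = 64) {
  list(A = test_projection(res),
       B = test_projection(res, dir = c(0, 0, 1), u_axis = c(-1, 0, 0)))
}

# smooth correlated random texture with an embedded bright patch
test_texture <- function(n = 128, seed = 2) {
  set.seed(seed)
  m <- matrix(0, n, n)
  k <- floor(n * 0.55)
  i0 <- floor(n * 0.22)
  m[i0:(i0 + k), i0:(i0 + k)] <- matrix(runif((k + 1)^2) * 200, k + 1)
  sm <- function(x) (x + x[c(1, 1:(n - 1)), ] + x[c(2:n, n), ] +
                       x[, c(1, 1:(n - 1))] + x[, c(2:n, n)]) / 5
  sm(sm(m))
}

# resample an image under a rigid 2D motion (oracle for tracker tests)
rigid_resample <- function(img, du = 0, dv = 0, theta_deg = 0,
                           center = (dim(img) - 1) / 2) {
  n <- nrow(img); m <- ncol(img)
  th <- theta_deg * pi / 180
  out <- img * 0
  for (r in 1:n) for (cc in 1:m) {
    a <- cc - 1 - center[1] - du
    b <- r - 1 - center[2] - dv
    u <- center[1] + cos(th) * a + sin(th) * b
    v <- center[2] - sin(th) * a + cos(th) * b
    i <- floor(v); j <- floor(u)
    if (i >= 0 && j >= 0 && i < n - 2 && j < m - 2) {
      fv <- v - i; fu <- u - j
      out[r, cc] <- img[i + 1, j + 1] * (1 - fv) * (1 - fu) +
        img[i + 2, j + 1] * fv * (1 - fu) +
        img[i + 1, j + 2] * (1 - fv) * fu +
        img[i + 2, j + 2] * fv * fu
    }
  }
  out
}

# cached 128 px scene shared across expensive tests
shared_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_scene(scene_config(), seed = 1)
    cache
  }
})

# flat triangulated plane z = 0 spanning [-half, half]^2 (open surface;
# used where a densely sampled plane-like slab is needed)
grid_plane <- function(half = 20, n = 21) {
  xs <- seq(-half, half, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  verts <- cbind(g$x, g$y, 0)
  faces <- list()
  for (i in 1:(n - 1)) for (j in 1:(n - 1)) {
    a <- (j - 1) * n + i
    faces[[length(faces) + 1]] <- c(a, a + 1, a + n)
    faces[[length(faces) + 1]] <- c(a + 1, a + n + 1, a + n)
  }
  surface_mesh(verts, do.call(rbind, faces))
}

rot_y_oracle <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

cross3_oracle <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

random_pose <- function() {
  pose6(runif(1, -20, 20), runif(1, -20, 20), runif(1, -20, 20),
        runif(1, -80, 80), runif(1, -80, 80), runif(1, -80, 80))
}
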