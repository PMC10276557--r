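#' Corresponded training set
#'
#' A collection of meshes sharing one topology (identical face lists and
#' vertex counts), vertex-wise corresponded across shapes.
#'
#' @param shapes list of `surface_mesh` objects with identical connectivity.
#' @param labels character identifiers (defaults to `shape_1, ...`).
#' @return An object of class `training_set`.
#' @export
training_set <- function(shapes, labels = NULL) {
  stopifnot(length(shapes) >= 1)
  f0 <- shapes[[1]]$faces
  for (s in shapes) {
    if (nrow(s$vertices) != nrow(shapes[[1]]$vertices) ||
        !identical(s$faces, f0))
      stop("all shapes must share the reference topology")
  }
  if (is.null(labels)) labels <- paste0("shape_", seq_along(shapes))
  structure(list(shapes = shapes, labels = labels), class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d shapes, %d vertices each\n",
              length(x$shapes), nrow(x$shapes[[1]]$vertices)))
  invisible(x)
}

# index of the nearest row of B for each row of A (ties: lowest index)
nearest_vertices <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  max.col(-d2, ties.method = "first")
}

#' Rigid iterative-closest-point alignment
#'
#' Point-to-point ICP with closest-vertex matching and trimming of the
#' worst residuals, aligning `src` onto `dst`.
#'
#' @param src,dst `surface_mesh` objects (or n x 3 matrices).
#' @param max_iter iteration cap.
#' @param trim fraction of best-matching points kept in each fit.
#' @param tol stop when the mean closest-point distance changes less than
#'   this (mm).
#' @return A `rigid_transform` mapping src into dst, with attributes
#'   `mean_distance` and `iterations`. Errors if the mean distance
#'   increases for 5 consecutive iterations (divergence).
#' @export
icp_rigid <- function(src, dst, max_iter = 50, trim = 0.95, tol = 1e-9) {
  S <- if (inherits(src, "surface_mesh")) src$vertices else as.matrix(src)
  D <- if (inherits(dst, "surface_mesh")) dst$vertices else as.matrix(dst)
  core <- function(init) {
    total <- init
    cur <- apply_transform(total, S)
    prev_d <- Inf
    bad <- 0
    for (it in seq_len(max_iter)) {
      nn <- nearest_vertices(cur, D)
      res <- sqrt(rowSums((cur - D[nn, , drop = FALSE])^2))
      keep <- order(res)[seq_len(max(3, floor(trim * length(res))))]
      fit <- rigid_point_fit(cur[keep, , drop = FALSE],
                             D[nn[keep], , drop = FALSE])
      total <- compose_transforms(fit, total)
      cur <- apply_transform(fit, cur)
      md <- mean(res)
      # count only meaningful growth; flat oscillation is convergence
      if (md > prev_d * (1 + 1e-3)) bad <- bad + 1 else bad <- 0
      if (bad >= 5)
        stop("rigid ICP diverged (distance increased 5 iterations)")
      if (abs(prev_d - md) < tol) break
      prev_d <- md
    }
    attr(total, "mean_distance") <- md
    attr(total, "iterations") <- it
    total
  }
  # two deterministic initializations: centroid shift, and principal-axes
  # alignment with skewness-based sign disambiguation; keep the better fit
  inits <- list(rigid_transform(diag(3), colMeans(D) - colMeans(S)),
                pca_align_init(S, D))
  fits <- lapply(inits, function(i) tryCatch(core(i), error = identity))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop(conditionMessage(fits[[1]]))
  fits <- fits[ok]
  fits[[which.min(vapply(fits, attr, numeric(1), "mean_distance"))]]
}

pca_align_init <- function(S, D) {
  frame_of <- function(V) {
    ctr <- colMeans(V)
    Vc <- sweep(V, 2, ctr)
    E <- eigen(stats::cov(Vc), symmetric = TRUE)$vectors
    for (k in 1:3) if (sum((Vc %*% E[, k])^3) < 0) E[, k] <- -E[, k]
    if (det(E) < 0) E[, 3] <- -E[, 3]
    list(ctr = ctr, E = E)
  }
  fs <- frame_of(S)
  fd <- frame_of(D)
  R0 <- fd$E %*% t(fs$E)
  rigid_transform(R0, fd$ctr - as.numeric(R0 %*% fs$ctr))
}

#' Establish dense correspondence between a reference and a target mesh
#'
#' Transfers the reference topology onto the target geometry: a trimmed
#' rigid ICP pre-alignment followed by a Gaussian-kernel-regularized
#' nonrigid registration in which each reference vertex is attracted to its
#' closest point on the target surface, with the displacement field
#' smoothed by a Gaussian kernel to keep the deformation coherent.
#'
#' @param reference `surface_mesh` providing the topology.
#' @param target `surface_mesh` providing the geometry.
#' @param iterations nonrigid iterations.
#' @param kernel_frac Gaussian kernel width as a fraction of the target
#'   bounding-box diagonal.
#' @param step displacement step per iteration (0..1].
#' @return A `surface_mesh` with the reference connectivity lying on the
#'   target surface; attribute `mean_surface_distance` reports the mean
#'   vertex-to-target-surface distance (mm).
#' @export
establish_correspondence <- function(reference, target, iterations = 30,
                                     kernel_frac = 0.10, step = 0.5) {
  d0 <- mean(cpp_closest_on_mesh(reference$vertices, target$vertices,
                                 target$faces)$distance)
  V <- if (d0 < 1e-6) {
    reference$vertices  # already on the surface: idempotent fast path
  } else {
    apply_transform(icp_rigid(reference, target), reference$vertices)
  }
  sigma <- kernel_frac * mesh_bbox_diag(target)
  # fixed kernel on the (pre-aligned) reference: coherent across iterations
  K <- exp(-as.matrix(stats::dist(V))^2 / (2 * sigma^2))
  K <- K / rowSums(K)
  for (it in seq_len(iterations)) {
    cp <- cpp_closest_on_mesh(V, target$vertices, target$faces)
    resid <- cp$closest - V
    V <- V + step * (K %*% resid)
  }
  cp <- cpp_closest_on_mesh(V, target$vertices, target$faces)
  # final unsmoothed snap keeps vertices exactly on the target surface
  V <- V + (cp$closest - V)
  out <- surface_mesh(V, reference$faces)
  cp2 <- cpp_closest_on_mesh(V, target$vertices, target$faces)
  attr(out, "mean_surface_distance") <- mean(cp2$distance)
  out
}

#' Generalized Procrustes alignment of a corresponded training set
#'
#' Iteratively removes translation and rotation (no scaling: bone size is a
#' genuine shape feature needed for reconstruction in mm) by aligning every
#' shape to the running mean until the mean changes less than `tol`.
#'
#' @param ts a `training_set`.
#' @param scale also normalize centroid size (off by default).
#' @param tol convergence tolerance on the mean shape (mm).
#' @param max_iter iteration cap.
#' @return List with `aligned` (a `training_set`) and `mean` (a
#'   `surface_mesh` of the converged mean shape).
#' @export
gpa_align <- function(ts, scale = FALSE, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(ts, "training_set"), length(ts$shapes) >= 2)
  faces <- ts$shapes[[1]]$faces
  mats <- lapply(ts$shapes, function(s) {
    v <- sweep(s$vertices, 2, colMeans(s$vertices))
    if (scale) v <- v / sqrt(sum(v^2))
    v
  })
  mref <- mats[[1]]
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, function(v) apply_transform(rigid_point_fit(v, mref), v))
    mnew <- Reduce(`+`, mats) / length(mats)
    delta <- sqrt(mean((mnew - mref)^2))
    mref <- mnew
    if (delta < tol && it > 1) break
  }
  aligned <- training_set(lapply(mats, surface_mesh, faces = faces),
                          ts$labels)
  list(aligned = aligned, mean = surface_mesh(mref, faces))
}

#' Statistical shape model
#'
#' Principal-component decomposition of a corresponded, aligned training
#' set: each training shape is the mean shape plus a linear combination of
#' orthonormal variation modes.
#'
#' @param aligned a `training_set` (output of [gpa_align()]).
#' @param n_modes number of retained modes (at most `n - 1`). The default
#'   20 mirrors the two-phase 10 + 10 reconstruction split.
#' @return An object of class `shape_model` with elements `mean_shape`
#'   (3V-vector, interleaved x,y,z per vertex), `modes` (3V x M orthonormal
#'   matrix), `eigenvalues` (mm^2, descending), `faces`, `V`, `M`.
#' @export
build_ssm <- function(aligned, n_modes = 20) {
  if (inherits(aligned, "list") && !is.null(aligned$aligned))
    aligned <- aligned$aligned
  stopifnot(inherits(aligned, "training_set"))
  n <- length(aligned$shapes)
  if (n_modes > n - 1)
    stop(sprintf("n_modes (%d) exceeds training size - 1 (%d)", n_modes,
                 n - 1))
  X <- t(vapply(aligned$shapes, function(s) as.numeric(t(s$vertices)),
                numeric(3 * nrow(aligned$shapes[[1]]$vertices))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n - 1, ncol(Xc)))
  ev <- (sv$d^2 / (n - 1))[seq_len(min(n - 1, length(sv$d)))]
  structure(list(mean_shape = mu,
                 modes = sv$v[, seq_len(n_modes), drop = FALSE],
                 eigenvalues = ev[seq_len(n_modes)],
                 all_eigenvalues = ev,
                 faces = aligned$shapes[[1]]$faces,
                 V = nrow(aligned$shapes[[1]]$vertices),
                 M = n_modes),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d vertices, %d modes, total variance %.3g mm^2\n",
              x$V, x$M, sum(x$all_eigenvalues)))
  invisible(x)
}

#' Synthesize a shape instance from mode coefficients
#'
#' @param model a `shape_model`.
#' @param b numeric coefficient vector (mm scale), length at most
#'   `model$M`; missing trailing modes are taken as 0.
#' @return A `surface_mesh` with the model topology.
#' @export
synthesize_shape <- function(model, b = numeric(0)) {
  k <- length(b)
  stopifnot(k <= model$M)
  v <- model$mean_shape
  if (k > 0)
    v <- v + as.numeric(model$modes[, seq_len(k), drop = FALSE] %*% b)
  surface_mesh(matrix(v, ncol = 3, byrow = TRUE), model$faces)
}

#' Project a corresponded shape onto the model subspace
#'
#' Least-squares mode coefficients of a mesh sharing the model topology.
#'
#' @param model a `shape_model`.
#' @param mesh a `surface_mesh` with `model$V` vertices.
#' @param n_modes number of modes used (default all retained).
#' @return Numeric coefficient vector.
#' @export
project_shape <- function(model, mesh, n_modes = model$M) {
  x <- as.numeric(t(mesh$vertices)) - model$mean_shape
  as.numeric(crossprod(model$modes[, seq_len(n_modes), drop = FALSE], x))
}

#' Save or load a shape model archive
#'
#' The model is serialized losslessly to a single JSON file with documented
#' fields (`mean_shape`, `modes`, `eigenvalues`, `faces`, `V`, `M`).
#'
#' @param model a `shape_model`.
#' @param path file path (`.json`).
#' @return `load_shape_model`: a `shape_model`; `save_shape_model`: the
#'   path, invisibly.
#' @export
save_shape_model <- function(model, path) {
  obj <- list(format = "aimtrack_shape_model_v1",
              mean_shape = model$mean_shape,
              modes = model$modes,
              eigenvalues = model$eigenvalues,
              all_eigenvalues = model$all_eigenvalues,
              faces = model$faces, V = model$V, M = model$M)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_shape_model
#' @export
load_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "aimtrack_shape_model_v1"))
    stop("not an aimtrack shape model archive: ", path)
  structure(list(mean_shape = as.numeric(obj$mean_shape),
                 modes = matrix(as.numeric(obj$modes), nrow = 3 * obj$V),
                 eigenvalues = as.numeric(obj$eigenvalues),
                 all_eigenvalues = as.numeric(obj$all_eigenvalues),
                 faces = matrix(as.integer(obj$faces), ncol = 3),
                 V = as.integer(obj$V), M = as.integer(obj$M)),
            class = "shape_model")
}
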