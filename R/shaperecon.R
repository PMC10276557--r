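#' Static acquisition set for shape reconstruction
#'
#' One, two or three bi-plane image pairs of the stationary subject, each
#' acquired at a different plate rotation, with rigid transforms mapping
#' the first pair's frame into each pair's frame.
#'
#' @param pairs list of pairs; each a list with `images` (list of two
#'   `radiograph`) and `models` (list of two `projection_model`).
#' @param pair_transforms list of `rigid_transform`, one per pair; the
#'   first must be the identity.
#' @return An object of class `acquisition_set`.
#' @export
acquisition_set <- function(pairs, pair_transforms = NULL) {
  stopifnot(length(pairs) >= 1)
  if (is.null(pair_transforms))
    pair_transforms <- replicate(length(pairs), rigid_transform(),
                                 simplify = FALSE)
  stopifnot(length(pair_transforms) == length(pairs))
  t1 <- pair_transforms[[1]]
  if (max(abs(t1$rotation - diag(3))) > 1e-9 ||
      max(abs(t1$translation)) > 1e-9)
    stop("pair_transforms[[1]] must be the identity")
  structure(list(pairs = pairs, pair_transforms = pair_transforms,
                 n_pairs = length(pairs)),
            class = "acquisition_set")
}

#' @export
print.acquisition_set <- function(x, ...) {
  cat(sprintf("acquisition_set: %d bi-plane pair(s)\n", x$n_pairs))
  invisible(x)
}

#' Derive inter-pair transforms from lead-marker observations
#'
#' Triangulates each lead marker per pair by radio-stereometric analysis
#' and rigidly co-registers each pair's marker cloud to the first pair's.
#'
#' @param marker_obs list (one element per pair) of lists with two n x 2
#'   pixel-coordinate matrices, one per plane (rows are markers, matched
#'   across planes and pairs).
#' @param models list of two `projection_model`s (fixed X-ray units).
#' @return List of `rigid_transform`s (first = identity), each with the
#'   marker-fit RMS in attribute `rms`.
#' @export
derive_pair_transforms <- function(marker_obs, models) {
  clouds <- lapply(marker_obs, function(obs) {
    n <- nrow(obs[[1]])
    if (n < 3) stop("need >= 3 markers visible in both planes of every pair")
    t(vapply(seq_len(n), function(i)
      triangulate_rsa(list(obs[[1]][i, ], obs[[2]][i, ]), models)$point,
      numeric(3)))
  })
  out <- vector("list", length(clouds))
  out[[1]] <- rigid_transform()
  attr(out[[1]], "rms") <- 0
  for (k in seq_along(clouds)[-1])
    out[[k]] <- rigid_point_fit(clouds[[1]], clouds[[k]])
  out
}

# views list for multiview_cost from an acquisition set
acq_views <- function(acq) {
  views <- list()
  for (k in seq_len(acq$n_pairs)) {
    pr <- acq$pairs[[k]]
    for (j in 1:2)
      views[[length(views) + 1]] <-
        list(image = pr$images[[j]], model = pr$models[[j]],
             transform = acq$pair_transforms[[k]])
  }
  views
}

recon_cost <- function(model, acq, pose_vec, b, spacing, dilate) {
  mesh <- synthesize_shape(model, b)
  vol <- voxelize_mesh(mesh, spacing = spacing)
  as.numeric(multiview_cost(vol, vec_to_pose(pose_vec), acq_views(acq),
                            dilate = dilate, step = min(vol$spacing) / 2))
}

#' Phase 1: joint pose and coarse shape search
#'
#' Sixteen-parameter genetic-algorithm search over the six pose parameters
#' and the first ten shape-mode coefficients (bounded at +/- 3 SD),
#' maximizing the summed gradient correlation between pseudo-DRRs of the
#' candidate shape and all acquired images. Candidates are voxelized at a
#' coarse spacing during the search for tractability.
#'
#' @param model a `shape_model` with at least 10 modes.
#' @param acq an `acquisition_set`.
#' @param init_pose initial `pose6` about which the pose box is centered
#'   (from static calibration or manual initialization).
#' @param settings a [search_settings()]; `pose_bounds` gives the pose box
#'   half-widths and `coeff_bound_sd` the coefficient bounds.
#' @param n_coeff number of leading modes searched (default 10).
#' @param ga_spacing voxelization spacing during the search (mm).
#' @param dilate similarity-region dilation (px).
#' @return List with `pose` (`pose6`), `coefficients` (length `n_coeff`),
#'   and `cost`.
#' @export
phase1_fit <- function(model, acq, init_pose = pose6(),
                       settings = search_settings(), n_coeff = 10,
                       ga_spacing = 1.0, dilate = NULL) {
  if (model$M < n_coeff)
    stop(sprintf("shape model has %d modes; phase 1 needs >= %d", model$M,
                 n_coeff))
  sdk <- sqrt(model$eigenvalues[seq_len(n_coeff)])
  v0 <- pose_to_vec(init_pose)
  lower <- c(v0 - settings$pose_bounds, -settings$coeff_bound_sd * sdk)
  upper <- c(v0 + settings$pose_bounds, settings$coeff_bound_sd * sdk)
  costf <- function(v) recon_cost(model, acq, v[1:6], v[-(1:6)], ga_spacing,
                                  dilate)
  res <- ga_optimize(costf, lower, upper, settings,
                     init = c(v0, rep(0, n_coeff)))
  list(pose = vec_to_pose(res$par[1:6]), coefficients = res$par[-(1:6)],
       cost = res$value)
}

#' Phase 2: shape refinement with ten additional modes
#'
#' Ten-parameter search over modes 11..20 only, holding the phase-1 pose
#' and leading coefficients fixed. The zero vector (i.e. the phase-1
#' solution) is seeded into the initial population, so with elitism the
#' refined objective can never be worse than phase 1's.
#'
#' @param model a `shape_model` with at least `n_coeff + n_extra` modes.
#' @param acq an `acquisition_set`.
#' @param phase1 result of [phase1_fit()].
#' @param settings a [search_settings()].
#' @param n_extra number of additional modes (default 10).
#' @param ga_spacing,dilate as in [phase1_fit()].
#' @return List with `pose`, `coefficients` (length
#'   `length(phase1$coefficients) + n_extra`) and `cost`.
#' @export
phase2_refine <- function(model, acq, phase1, settings = search_settings(),
                          n_extra = 10, ga_spacing = 1.0, dilate = NULL) {
  n1 <- length(phase1$coefficients)
  if (model$M < n1 + n_extra)
    stop(sprintf("shape model has %d modes; phase 2 needs >= %d", model$M,
                 n1 + n_extra))
  sdk <- sqrt(model$eigenvalues[n1 + seq_len(n_extra)])
  lower <- -settings$coeff_bound_sd * sdk
  upper <- settings$coeff_bound_sd * sdk
  pv <- pose_to_vec(phase1$pose)
  costf <- function(v) recon_cost(model, acq, pv,
                                  c(phase1$coefficients, v), ga_spacing,
                                  dilate)
  res <- ga_optimize(costf, lower, upper, settings, init = rep(0, n_extra))
  list(pose = phase1$pose,
       coefficients = c(phase1$coefficients, res$par),
       cost = res$value)
}

#' Reconstruct a subject-specific bone model from static image pairs
#'
#' Runs the two-phase optimization (pose + 10 modes, then 10 further
#' modes) and synthesizes the final subject-specific mesh, voxelizing the
#' result at the full evaluation resolution.
#'
#' @param model a `shape_model`.
#' @param acq an `acquisition_set`.
#' @param init_pose initial `pose6`.
#' @param settings a [search_settings()].
#' @param two_phase run phase 2 (requires >= 20 modes).
#' @param ga_spacing candidate voxel spacing during the search (mm).
#' @param final_spacing voxel spacing of the returned volume (mm).
#' @param dilate similarity-region dilation (px).
#' @param truth_mesh optional ground-truth mesh; when given, RMSe
#'   diagnostics are computed per phase.
#' @return List with `mesh`, `pose`, `coefficients`, `volume` and
#'   `diagnostics` (per-phase costs and RMSe when truth is available).
#' @export
reconstruct_subject_model <- function(model, acq, init_pose = pose6(),
                                      settings = search_settings(),
                                      two_phase = TRUE, ga_spacing = 1.0,
                                      final_spacing = 0.5, dilate = NULL,
                                      truth_mesh = NULL) {
  if (!inherits(acq, "acquisition_set") || acq$n_pairs < 1)
    stop("empty acquisition set")
  p1 <- phase1_fit(model, acq, init_pose, settings, ga_spacing = ga_spacing,
                   dilate = dilate)
  diag <- list(phase1_cost = p1$cost)
  if (!is.null(truth_mesh))
    diag$phase1_rmse <- as.numeric(shape_rmse(
      synthesize_shape(model, p1$coefficients), truth_mesh))
  fit <- p1
  if (two_phase) {
    fit <- phase2_refine(model, acq, p1, settings, ga_spacing = ga_spacing,
                         dilate = dilate)
    diag$phase2_cost <- fit$cost
    if (!is.null(truth_mesh))
      diag$phase2_rmse <- as.numeric(shape_rmse(
        synthesize_shape(model, fit$coefficients), truth_mesh))
  }
  mesh <- synthesize_shape(model, fit$coefficients)
  list(mesh = mesh, pose = fit$pose, coefficients = fit$coefficients,
       volume = voxelize_mesh(mesh, spacing = final_spacing),
       diagnostics = diag)
}
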