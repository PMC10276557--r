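#' Interleaved bi-plane sequence
#'
#' Time-stamped frames alternating strictly between the two X-ray units
#' (planes A and B), each frame acquired at its own instant — no two
#' frames are simultaneous. The clinical default is 30 fps per plane with
#' a constant 1/60 s inter-unit offset (60 fps effective).
#'
#' @param frames ordered list of `radiograph`s with `plane_id` and
#'   `timestamp` set.
#' @param fps per-plane frame rate.
#' @param offset inter-unit time offset (s).
#' @return An object of class `interleaved_sequence`.
#' @export
interleaved_sequence <- function(frames, fps = 30, offset = 1 / 60) {
  ids <- vapply(frames, function(f) f$plane_id, character(1))
  if (length(frames) >= 2 && any(ids[-1] == ids[-length(ids)]))
    stop("plane ids must strictly alternate")
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (any(diff(ts) <= 0)) stop("timestamps must strictly increase")
  structure(list(frames = frames, fps = fps, offset = offset),
            class = "interleaved_sequence")
}

#' @export
print.interleaved_sequence <- function(x, ...) {
  cat(sprintf("interleaved_sequence: %d frames, %g fps/plane, offset %g s\n",
              length(x$frames), x$fps, x$offset))
  invisible(x)
}

#' Particle-filter tracker state
#'
#' @param n_particles particle count.
#' @param sd random-walk standard deviations `(px, px, deg)` for
#'   `(du, dv, dtheta)`.
#' @return An object of class `tracker_state` with a particle matrix and
#'   uniform weights.
#' @export
tracker_state <- function(n_particles = 300, sd = c(2, 2, 1)) {
  structure(list(particles = matrix(0, n_particles, 3),
                 weights = rep(1 / n_particles, n_particles),
                 sd = sd),
            class = "tracker_state")
}

#' 2D template registration with a particle filter
#'
#' Estimates the in-plane pose increment `(du, dv, dtheta)` of a template
#' region between two frames of the same plane. Particles propagate by a
#' random walk, are weighted by an NCC-based template-match likelihood
#' (`exp(NCC / tau)`), and are resampled systematically.
#'
#' @param prev_frame,cur_frame `radiograph`s from the same plane.
#' @param template_region 0-based inclusive pixel window `c(u0, u1, v0,
#'   v1)` inside both images.
#' @param state a `tracker_state`.
#' @param tau likelihood temperature.
#' @param iterations propagate/weight/resample sweeps per frame pair (the
#'   random-walk scale halves each sweep, letting particles migrate to the
#'   likelihood mode).
#' @return List with `increment` `(du px, dv px, dtheta deg)` and the
#'   updated `state`. Errors when all template-match likelihoods vanish
#'   (track lost).
#' @export
template_track_2d <- function(prev_frame, cur_frame, template_region,
                              state = tracker_state(), tau = 0.01,
                              iterations = 3) {
  A <- prev_frame$pixels; B <- cur_frame$pixels
  if (!identical(prev_frame$plane_id, cur_frame$plane_id) &&
      !is.na(prev_frame$plane_id) && !is.na(cur_frame$plane_id))
    stop("frames must come from the same plane")
  r <- template_region
  cu <- (r[1] + r[2]) / 2; cv <- (r[3] + r[4]) / 2
  hu <- max(2, floor((r[2] - r[1]) / 2)); hv <- max(2, floor((r[4] - r[3]) / 2))
  np <- nrow(state$particles)
  part <- state$particles
  inc <- c(0, 0, 0)
  for (it in seq_len(iterations)) {
    sdk <- state$sd / 2^(it - 1)
    part <- part + cbind(rnorm(np, 0, sdk[1]), rnorm(np, 0, sdk[2]),
                         rnorm(np, 0, sdk[3]))
    ncc <- cpp_particle_ncc(A, B, cu, cv, hu, hv, part)
    lik <- exp((ncc - max(ncc)) / tau)
    if (all(ncc <= -1 + 1e-12) || sum(lik) <= 0)
      stop("track lost: all template-match likelihoods are zero")
    w <- lik / sum(lik)
    inc <- as.numeric(crossprod(w, part))
    # systematic resampling
    u0 <- runif(1) / np
    cdf <- cumsum(w)
    idx <- findInterval(u0 + (0:(np - 1)) / np, cdf) + 1
    idx[idx > np] <- np
    part <- part[idx, , drop = FALSE]
  }
  state$particles <- sweep(part, 2, colMeans(part))  # dispersion, centered
  state$weights <- rep(1 / np, np)
  list(increment = inc, state = state)
}

rodrigues <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Predict a 3D pose from per-plane 2D increments
#'
#' Back-projects the in-plane increments of the two views to a 3D pose
#' increment: translation increments are summed over views as
#' `(du*u_axis + dv*v_axis) * pixel_spacing / magnification` (magnification
#' evaluated at the object centroid depth along each view's principal
#' ray); in-plane rotations become rotations about each view's principal
#' axis and are composed. The increment is applied to the previous pose.
#'
#' @param inc_A,inc_B increments `(du, dv, dtheta)` from planes A and B.
#' @param models list of the two `projection_model`s (A, B).
#' @param prev_pose the previous frame's `pose6`.
#' @param centroid model-frame centroid of the tracked bone (mm).
#' @return The predicted `pose6`.
#' @export
increments_to_3d <- function(inc_A, inc_B, models, prev_pose,
                             centroid = c(0, 0, 0)) {
  prev_tr <- pose_to_transform(prev_pose)
  obj <- apply_transform(prev_tr, centroid)
  dt <- c(0, 0, 0)
  Rinc <- diag(3)
  incs <- list(inc_A, inc_B)
  for (k in 1:2) {
    m <- models[[k]]
    n <- m$normal  # detector normal, toward the source
    depth <- abs(sum((m$source - obj) * n))
    mag <- m$sdd / max(depth, 1e-6)
    inc <- incs[[k]]
    dt <- dt + (inc[1] * m$pixel_spacing[1] * m$u_axis +
                  inc[2] * m$pixel_spacing[2] * m$v_axis) / mag
    # in-plane rotation maps to rotation about the principal (normal) axis;
    # u x v = n, so image-plane rotation u->v is a rotation about +n
    Rinc <- rodrigues(n, inc[3]) %*% Rinc
  }
  newR <- Rinc %*% prev_tr$rotation
  # rotate about the object centroid, not the model origin
  newt <- obj + dt - as.numeric(Rinc %*% (obj - prev_tr$translation))
  transform_to_pose(rigid_transform(newR, newt))
}

median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(m)
  out <- m
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1))
    out[i, j] <- stats::median(m[(i - 1):(i + 1), (j - 1):(j + 1)])
  out
}

#' Motion-compensated midpoint frame interpolation
#'
#' Synthesizes the intermediate frame between two consecutive same-plane
#' frames: hierarchical block matching (coarse then fine blocks) estimates
#' a dense displacement field, which is median-smoothed; both frames are
#' then warped halfway along the motion and blended. When the two frames
#' are essentially uncorrelated the method falls back to plain averaging
#' and sets the `degenerate` flag.
#'
#' @param prev,nxt `radiograph`s from the same plane (consecutive frames).
#' @param blocks block sizes of the hierarchy (px).
#' @param radius search radius per level (px).
#' @return The midpoint `radiograph` (timestamp = midpoint), with
#'   attribute `degenerate`.
#' @export
interpolate_frame <- function(prev, nxt, blocks = c(16, 8), radius = 8) {
  A <- prev$pixels; B <- nxt$pixels
  stopifnot(all(dim(A) == dim(B)))
  ts <- (prev$timestamp + nxt$timestamp) / 2
  corr <- tryCatch(stats::cor(as.numeric(A), as.numeric(B)),
                   warning = function(w) 0)
  if (is.na(corr)) corr <- if (max(abs(A - B)) < 1e-12) 1 else 0
  if (corr < 0.2) {
    out <- radiograph((A + B) / 2, prev$plane_id, ts, prev$bit_depth)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  empty <- matrix(0, 0, 0)
  fu <- empty; fv <- empty
  for (bs in blocks) {
    bm <- cpp_block_match(A, B, bs, radius, up_block(fu, A, bs),
                          up_block(fv, A, bs))
    fu <- median_filter3(bm$flow_u)
    fv <- median_filter3(bm$flow_v)
    attr(fu, "block") <- bs
  }
  bs <- blocks[length(blocks)]
  FU <- up_pixel(fu, dim(A), bs)
  FV <- up_pixel(fv, dim(A), bs)
  # backward warping: sample prev halfway forward, nxt halfway backward
  WA <- cpp_warp(A, FU, FV, -0.5)
  WB <- cpp_warp(B, FU, FV, 0.5)
  out <- radiograph((WA + WB) / 2, prev$plane_id, ts, prev$bit_depth)
  attr(out, "degenerate") <- FALSE
  out
}

# upsample a per-block field to the block grid of size `bs` over image A
up_block <- function(f, A, bs) {
  if (length(f) == 0) return(matrix(0, 0, 0))
  prev_bs <- attr(f, "block")
  nbv <- nrow(A) %/% bs; nbu <- ncol(A) %/% bs
  ratio <- prev_bs / bs
  i <- pmin(nrow(f), pmax(1, ceiling((1:nbv) / ratio)))
  j <- pmin(ncol(f), pmax(1, ceiling((1:nbu) / ratio)))
  f[i, j, drop = FALSE]
}

# nearest-neighbour upsample block field to pixel resolution
up_pixel <- function(f, dims, bs) {
  i <- pmin(nrow(f), pmax(1, ceiling((1:dims[1]) / bs)))
  j <- pmin(ncol(f), pmax(1, ceiling((1:dims[2]) / bs)))
  f[i, j, drop = FALSE]
}

#' Track a bone through an interleaved bi-plane sequence (AIMT)
#'
#' The three-stage alternating interpolation-based model tracking. For
#' each frame: (1) the 2D pose increments of the bone in both planes are
#' estimated by particle-filter template registration and combined into a
#' 3D pose prediction; (2) the partner plane's image at the frame's
#' instant is synthesized by motion-compensated interpolation of its two
#' neighbouring frames, forming a pseudo-synchronous bi-plane pair; (3)
#' the predicted pose is refined by bi-plane 3D/2D gradient-correlation
#' registration. The first frame takes the supplied initial pose (from
#' static calibration); the last frame is paired with the nearest partner
#' frame and flagged.
#'
#' @param volume `voxel_volume` of the tracked bone (model coordinates).
#' @param seq an `interleaved_sequence` (plane A first).
#' @param init_pose registered `pose6` of the first frame.
#' @param models list of the two `projection_model`s, named `A` and `B`.
#' @param settings a [search_settings()] for the per-frame registration;
#'   the default uses a compact budget with a Nelder-Mead polish.
#' @param n_particles,template_dilate particle filter size and template
#'   region dilation (px).
#' @param use_interpolation synthesize pseudo-synchronous partners (TRUE);
#'   FALSE pairs each frame with the nearest partner frame instead (naive
#'   baseline for comparisons).
#' @param seed RNG seed for the whole track.
#' @return A `tracking_result`: data frame `frames` (frame, time, plane,
#'   pose columns, cost, flags) and list `poses` of per-frame `pose6`.
#' @export
track_sequence <- function(volume, seq, init_pose, models,
                           settings = search_settings(
                             pop_size = 32, generations = 10,
                             polish = TRUE, polish_maxit = 60,
                             pose_bounds = c(3, 3, 3, 3, 3, 3)),
                           n_particles = 300, template_dilate = NULL,
                           use_interpolation = TRUE, seed = NULL) {
  frames <- seq$frames
  n <- length(frames)
  if (n == 0)
    return(structure(list(frames = data.frame(), poses = list()),
                     class = "tracking_result"))
  if (!is.null(seed)) set.seed(seed)
  centroid <- volume$origin + (dim(volume$values) - 1) * volume$spacing / 2
  poses <- vector("list", n)
  flags <- character(n)
  costs <- rep(NA_real_, n)
  poses[[1]] <- init_pose
  flags[1] <- "init"
  states <- list(A = tracker_state(n_particles),
                 B = tracker_state(n_particles))
  ids <- vapply(frames, function(f) f$plane_id, character(1))
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  for (i in seq_len(n)[-1]) {
    P <- ids[i]
    Q <- setdiff(c("A", "B"), P)
    prev_pose <- poses[[i - 1]]
    prev_tr <- pose_to_transform(prev_pose)
    # stage 1: particle-filter template increments on both planes
    # template margin: 5 mm on the detector (8 px at clinical resolution)
    tdl <- function(m) if (is.null(template_dilate))
      max(2L, as.integer(ceiling(5 / m$pixel_spacing[1]))) else
        template_dilate
    regP <- volume_roi(volume, prev_tr, models[[P]], dilate = tdl(models[[P]]))
    regQ <- volume_roi(volume, prev_tr, models[[Q]], dilate = tdl(models[[Q]]))
    incP <- c(0, 0, 0); incQ <- c(0, 0, 0)
    lost <- FALSE
    if (i >= 3) {
      tp <- tryCatch(
        template_track_2d(frames[[i - 2]], frames[[i]], regP, states[[P]]),
        error = function(e) NULL)
      if (is.null(tp)) lost <- TRUE else {
        incP <- tp$increment; states[[P]] <- tp$state
      }
    }
    if (i + 1 <= n) {
      tq <- tryCatch(
        template_track_2d(frames[[i - 1]], frames[[i + 1]], regQ,
                          states[[Q]]),
        error = function(e) NULL)
      if (is.null(tq)) lost <- TRUE else {
        incQ <- tq$increment; states[[Q]] <- tq$state
      }
    }
    # increments span two inter-frame intervals; halve for one step
    incs <- list(A = c(0, 0, 0), B = c(0, 0, 0))
    incs[[P]] <- incP / 2
    incs[[Q]] <- incQ / 2
    pred <- increments_to_3d(incs$A, incs$B, list(models$A, models$B),
                             prev_pose, centroid)
    # stage 2: pseudo-synchronous partner image on plane Q
    if (use_interpolation && i > 1 && i < n) {
      partner <- interpolate_frame(frames[[i - 1]], frames[[i + 1]])
      flags[i] <- if (lost) "widened" else "interpolated"
    } else {
      j <- if (i < n) i + 1 else i - 1
      partner <- frames[[j]]
      flags[i] <- "nearest"
    }
    # stage 3: bi-plane 3D/2D registration on the pseudo-synchronous pair
    pair <- list(list(image = frames[[i]], model = models[[P]]),
                 list(image = partner, model = models[[Q]]))
    st <- settings
    if (lost) st$pose_bounds <- 2 * st$pose_bounds
    reg <- tryCatch(
      biplane_register(volume, pred, pair, st),
      error = function(e) NULL)
    if (is.null(reg)) {  # continue from last good pose, widened search
      st$pose_bounds <- 2 * settings$pose_bounds
      reg <- biplane_register(volume, prev_pose, pair, st)
      flags[i] <- "widened"
    }
    poses[[i]] <- reg
    costs[i] <- attr(reg, "cost")
  }
  pm <- t(vapply(poses, pose_to_vec, numeric(6)))
  colnames(pm) <- c("x", "y", "z", "alpha", "beta", "gamma")
  structure(list(
    frames = data.frame(frame = seq_len(n), time = ts, plane = ids, pm,
                        cost = costs, flag = flags),
    poses = poses),
    class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("tracking_result: %d frames (%d interpolated, %d flagged)\n",
              nrow(x$frames), sum(x$frames$flag == "interpolated"),
              sum(!x$frames$flag %in% c("interpolated", "init"))))
  invisible(x)
}
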