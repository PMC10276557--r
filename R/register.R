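#' Bi-plane 3D/2D registration of a posed volume
#'
#' Searches the six pose parameters minimizing the summed negative gradient
#' correlation over the two views with a genetic algorithm, inside a box of
#' half-widths `settings$pose_bounds` centered on the initial pose (or
#' inside absolute bounds when supplied). With `settings$polish` a final
#' Nelder-Mead descent refines the GA optimum.
#'
#' @param volume a `voxel_volume`.
#' @param init initial `pose6` (must lie inside the bounds).
#' @param pair list of two views, each a list with `image` and `model` (and
#'   optionally `transform`), as in [multiview_cost()].
#' @param settings a [search_settings()].
#' @param lower,upper optional absolute length-6 pose bounds overriding the
#'   box around `init`.
#' @param dilate,step forwarded to [multiview_cost()].
#' @return The registered `pose6`, with attributes `cost` (the summed
#'   -f_GC at the optimum) and `trace`.
#' @export
biplane_register <- function(volume, init, pair, settings = search_settings(),
                             lower = NULL, upper = NULL, dilate = NULL,
                             step = min(volume$spacing) / 2) {
  v0 <- pose_to_vec(init)
  if (is.null(lower) || is.null(upper)) {
    lower <- v0 - settings$pose_bounds
    upper <- v0 + settings$pose_bounds
  }
  if (any(v0 < lower) || any(v0 > upper))
    stop("initial pose lies outside the search bounds")
  costf <- function(v)
    as.numeric(multiview_cost(volume, vec_to_pose(v), pair,
                              dilate = dilate, step = step))
  res <- ga_optimize(costf, lower, upper, settings, init = v0)
  out <- vec_to_pose(res$par)
  attr(out, "cost") <- res$value
  attr(out, "trace") <- res$trace
  out
}
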