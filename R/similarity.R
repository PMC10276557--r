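#' Sobel gradient images
#'
#' Applies the standard 3x3 horizontal and vertical Sobel templates.
#' Border pixels are left at zero and are excluded from similarity sums.
#'
#' @param img numeric matrix (rows = v, columns = u).
#' @return List with `gi` (horizontal derivative, along u) and `gj`
#'   (vertical derivative, along v), both the size of `img`.
#' @export
sobel_gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gi <- matrix(0, nr, nc); gj <- matrix(0, nr, nc)
  if (nr < 3 || nc < 3) return(list(gi = gi, gj = gj))
  r <- 2:(nr - 1); c <- 2:(nc - 1)
  # horizontal Sobel: d/du, kernel rows (1,2,1) smoothing, cols (-1,0,1)
  gi[r, c] <- (img[r - 1, c + 1] + 2 * img[r, c + 1] + img[r + 1, c + 1]) -
    (img[r - 1, c - 1] + 2 * img[r, c - 1] + img[r + 1, c - 1])
  # vertical Sobel: d/dv
  gj[r, c] <- (img[r + 1, c - 1] + 2 * img[r + 1, c] + img[r + 1, c + 1]) -
    (img[r - 1, c - 1] + 2 * img[r - 1, c] + img[r - 1, c + 1])
  list(gi = gi, gj = gj)
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(a^2); vb <- sum(b^2)
  if (va <= 1e-12 || vb <= 1e-12)
    stop("zero gradient variance in similarity region (flat image)")
  sum(a * b) / sqrt(va * vb)
}

#' Gradient-correlation similarity between a DRR and a fluoroscopic image
#'
#' The similarity is the sum of the normalized cross-correlations between
#' the horizontal and between the vertical Sobel-gradient images of the two
#' frames, each term mean-subtracted and variance-normalized over the
#' evaluation region. It ranges over \[-2, 2\], equals exactly 2 for
#' identical (non-flat) images, and is invariant to positive affine
#' intensity maps of either image.
#'
#' @param drr,fluoro `radiograph`s (or plain matrices) of equal dimensions.
#' @param region optional 0-based inclusive pixel window
#'   `c(u0, u1, v0, v1)`; defaults to the whole image. The window is
#'   intersected with the Sobel-valid interior.
#' @return List of class `similarity_result`: `f_gc`, `horizontal`,
#'   `vertical`, `region`.
#' @export
gradient_correlation <- function(drr, fluoro, region = NULL) {
  A <- if (inherits(drr, "radiograph")) drr$pixels else drr
  B <- if (inherits(fluoro, "radiograph")) fluoro$pixels else fluoro
  if (!all(dim(A) == dim(B))) stop("images must have identical dimensions")
  if (is.null(region)) region <- c(0, ncol(A) - 1, 0, nrow(A) - 1)
  # clip to Sobel-valid interior (border pixels excluded)
  u0 <- max(region[1], 1); u1 <- min(region[2], ncol(A) - 2)
  v0 <- max(region[3], 1); v1 <- min(region[4], nrow(A) - 2)
  if (u1 - u0 < 2 || v1 - v0 < 2) stop("similarity region too small")
  ga <- sobel_gradients(A); gb <- sobel_gradients(B)
  rows <- (v0 + 1):(v1 + 1); cols <- (u0 + 1):(u1 + 1)
  h <- ncc(ga$gi[rows, cols], gb$gi[rows, cols])
  v <- ncc(ga$gj[rows, cols], gb$gj[rows, cols])
  structure(list(f_gc = h + v, horizontal = h, vertical = v,
                 region = c(u0, u1, v0, v1)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("f_GC = %.6f (horizontal %.6f + vertical %.6f)\n",
              x$f_gc, x$horizontal, x$vertical))
  invisible(x)
}

#' Multi-view registration cost
#'
#' The cost minimized by the 3D/2D registration: the sum over the N views
#' of the negative gradient correlation between the DRR of the posed volume
#' and that view's fluoroscopic image (lower is better; -2N at perfect
#' similarity).
#'
#' @param volume a `voxel_volume`.
#' @param pose a `pose6` shared by all views (expressed in the common
#'   frame).
#' @param views list of views; each a list with elements `image`
#'   (`radiograph`), `model` (`projection_model`) and optionally
#'   `transform` (a `rigid_transform` mapping the common frame into the
#'   view's acquisition frame; identity when absent).
#' @param dilate silhouette-ROI dilation in pixels; the default `NULL`
#'   uses a fixed 6.25 mm physical margin (10 px at the clinical 0.625
#'   mm/px detector resolution), so the evaluated region keeps the same
#'   physical extent at reduced test resolutions and excludes static
#'   background and neighbouring-bone clutter.
#' @param step DRR ray step (mm); default half the smallest voxel spacing.
#' @return Scalar cost with attribute `per_view` (the f_GC values).
#' @export
multiview_cost <- function(volume, pose, views,
                           dilate = NULL, step = min(volume$spacing) / 2) {
  stopifnot(length(views) >= 1)
  base <- pose_to_transform(pose)
  f <- numeric(length(views))
  for (k in seq_along(views)) {
    vw <- views[[k]]
    tr <- if (is.null(vw$transform)) base else
      compose_transforms(vw$transform, base)
    dl <- if (is.null(dilate)) roi_margin_px(vw$model) else dilate
    drr <- generate_drr(volume, tr, vw$model, step = step, dilate = dl)
    f[k] <- gradient_correlation(drr, vw$image,
                                 region = attr(drr, "roi"))$f_gc
  }
  structure(-sum(f), per_view = f)
}

# similarity-region margin: 6.25 mm on the detector, at least 3 px
roi_margin_px <- function(model) {
  max(3L, as.integer(ceiling(6.25 / model$pixel_spacing[1])))
}
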