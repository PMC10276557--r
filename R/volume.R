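#' Voxel volume
#'
#' A regular 3D grid of attenuation surrogates (Hounsfield units). Voxel
#' centers lie at `origin + (index - 1) * spacing` (1-based indices).
#'
#' @param values 3D numeric array.
#' @param origin length-3 position of the first voxel center (mm).
#' @param spacing length-3 voxel spacing (mm), all positive.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, origin, spacing) {
  stopifnot(length(dim(values)) == 3, length(origin) == 3,
            length(spacing) == 3, all(spacing > 0))
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_volume: %dx%dx%d, spacing %.3gx%.3gx%.3g mm, [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxelize a watertight surface mesh into a pseudo-volumetric model
#'
#' Interior voxels receive a constant bone attenuation surrogate and
#' exterior voxels an air value, emulating a homogeneous-density CT volume.
#' Interior/exterior labeling is by ray-crossing parity along slice rows,
#' with the voxel lattice offset half a voxel from the mesh bounding box so
#' rays cannot graze vertices at exact grid coordinates.
#'
#' @param mesh a watertight `surface_mesh` (mm).
#' @param spacing voxel size in mm (scalar or length 3); default 0.5.
#' @param bone_value interior value (HU); default 700.
#' @param air_value exterior value (HU); default -1000.
#' @param pad voxels of air padding around the bounding box.
#' @return A `voxel_volume`.
#' @export
voxelize_mesh <- function(mesh, spacing = 0.5, bone_value = 700,
                          air_value = -1000, pad = 2) {
  if (nrow(mesh$faces) == 0) stop("empty mesh cannot be voxelized")
  wt <- is_watertight(mesh)
  if (!isTRUE(wt)) {
    oe <- attr(wt, "open_edges")
    stop(sprintf("mesh is not watertight: %d open/non-manifold edges (first: %s)",
                 nrow(oe), paste(oe[1, ], collapse = "-")))
  }
  spacing <- rep(spacing, length.out = 3)
  res <- cpp_voxelize(mesh$vertices, mesh$faces, spacing, bone_value,
                      air_value, pad)
  voxel_volume(array(res$values, dim = res$dim), res$origin, res$spacing)
}

#' Radiograph image
#'
#' A single fluoroscopic or DRR frame. Pixels are stored as a matrix with
#' rows indexing `v` (downward) and columns `u` (rightward), matching the
#' 0-based pixel convention of [projection_model()].
#'
#' @param pixels numeric matrix of intensities.
#' @param plane_id `"A"` or `"B"` (or `NA`).
#' @param timestamp acquisition time in seconds (or `NA`).
#' @param bit_depth `"float"` or `"8bit"`.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, plane_id = NA_character_,
                       timestamp = NA_real_, bit_depth = "float") {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels, plane_id = plane_id,
                 timestamp = timestamp, bit_depth = bit_depth),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("radiograph: %dx%d px (%s), plane %s, t = %s s\n",
              ncol(x$pixels), nrow(x$pixels), x$bit_depth, x$plane_id,
              format(x$timestamp)))
  invisible(x)
}

#' Quantize a float radiograph to 8 bits
#'
#' Affine min-max normalization to 0..255 followed by rounding. Gradient
#' correlation is invariant to positive affine intensity maps, so this
#' emulation of the fluoroscope's 8-bit output cannot bias registration.
#'
#' @param rg a `radiograph`.
#' @param lo,hi intensity range mapped to 0..255; defaults to the image
#'   range (a fixed range gives consistent gain across frames).
#' @return An 8-bit `radiograph`.
#' @export
quantize_8bit <- function(rg, lo = NULL, hi = NULL) {
  px <- rg$pixels
  if (is.null(lo)) lo <- min(px)
  if (is.null(hi)) hi <- max(px)
  if (hi <= lo) hi <- lo + 1
  q <- round(pmin(pmax((px - lo) / (hi - lo), 0), 1) * 255)
  radiograph(q, rg$plane_id, rg$timestamp, bit_depth = "8bit")
}

# Project the posed volume's bounding-box corners and return the 0-based
# inclusive pixel ROI c(u0, u1, v0, v1), dilated and clipped to the image.
volume_roi <- function(volume, transform, model, dilate = 10) {
  d <- dim(volume$values)
  lo <- volume$origin
  hi <- volume$origin + (d - 1) * volume$spacing
  corners <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                   z = c(lo[3], hi[3])))
  uv <- project_point(model, apply_transform(transform, corners))
  roi <- c(floor(min(uv[, 1])) - dilate, ceiling(max(uv[, 1])) + dilate,
           floor(min(uv[, 2])) - dilate, ceiling(max(uv[, 2])) + dilate)
  c(max(0, roi[1]), min(model$resolution[1] - 1, roi[2]),
    max(0, roi[3]), min(model$resolution[2] - 1, roi[4]))
}

#' Render a digitally reconstructed radiograph (DRR)
#'
#' Casts a ray from the X-ray point source to each detector pixel and
#' accumulates the line integral of `(value - air_value)` through the posed
#' volume, sampled with trilinear interpolation at a fixed step (default
#' half the smallest voxel spacing). Pixels whose rays miss the volume get
#' the background value 0.
#'
#' @param volume a `voxel_volume` in model coordinates.
#' @param pose a `pose6` or `rigid_transform` placing the model in the
#'   laboratory frame.
#' @param model a `projection_model`.
#' @param roi optional 0-based inclusive pixel window `c(u0, u1, v0, v1)`;
#'   default is the projected bounding box of the volume dilated by
#'   `dilate` pixels.
#' @param step ray sampling step in mm.
#' @param dilate ROI dilation in pixels when `roi` is automatic.
#' @param air_value attenuation of air subtracted before integration.
#' @return A float `radiograph` of the full detector resolution, with
#'   attribute `roi`.
#' @export
generate_drr <- function(volume, pose, model, roi = NULL,
                         step = min(volume$spacing) / 2, dilate = 10,
                         air_value = NULL) {
  tr <- if (inherits(pose, "pose6")) pose_to_transform(pose) else pose
  if (is.null(air_value)) air_value <- min(volume$values)
  if (is.null(roi)) roi <- volume_roi(volume, tr, model, dilate)
  px <- cpp_render_drr(as.numeric(volume$values), dim(volume$values),
                       volume$origin, volume$spacing, tr$rotation,
                       tr$translation, model$source, model$detector_origin,
                       model$u_axis, model$v_axis, model$pixel_spacing,
                       model$resolution, as.integer(roi), step, air_value)
  out <- radiograph(px)
  attr(out, "roi") <- roi
  out
}

#' Read and write voxel volumes as NIfTI
#'
#' @param volume a `voxel_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: a `voxel_volume`; `write_volume`: the path,
#'   invisibly.
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  aff <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               origin = aff[1:3, 4], spacing = diag(aff)[1:3])
}
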