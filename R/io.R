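#' Read and write projection-model calibrations as JSON
#'
#' The calibration file holds one object per X-ray unit (named `A`, `B`,
#' ...), each with `source`, `detector_origin`, `u_axis`, `v_axis`,
#' `pixel_spacing` and `resolution` fields.
#'
#' @param models named list of `projection_model`s.
#' @param path file path (`.json`).
#' @return `read_calibration`: named list of `projection_model`s;
#'   `write_calibration`: the path, invisibly.
#' @export
write_calibration <- function(models, path) {
  obj <- lapply(models, function(m)
    list(source = m$source, detector_origin = m$detector_origin,
         u_axis = m$u_axis, v_axis = m$v_axis,
         pixel_spacing = m$pixel_spacing, resolution = m$resolution))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(m)
    projection_model(m$source, m$detector_origin, m$u_axis, m$v_axis,
                     m$pixel_spacing, m$resolution))
}

#' Write and read per-frame pose series as CSV
#'
#' Fixed column order: `frame, t, x, y, z, alpha, beta, gamma`
#' (mm and degrees).
#'
#' @param poses list of `pose6`.
#' @param times per-frame times (s).
#' @param path file path (`.csv`).
#' @return `read_pose_csv`: list with `poses` and `times`;
#'   `write_pose_csv`: the path, invisibly.
#' @export
write_pose_csv <- function(poses, times, path) {
  pm <- t(vapply(poses, pose_to_vec, numeric(6)))
  df <- data.frame(frame = seq_along(poses), t = times,
                   x = pm[, 1], y = pm[, 2], z = pm[, 3],
                   alpha = pm[, 4], beta = pm[, 5], gamma = pm[, 6])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path)
  list(poses = lapply(seq_len(nrow(df)), function(i)
    pose6(df$x[i], df$y[i], df$z[i], df$alpha[i], df$beta[i], df$gamma[i])),
    times = df$t)
}

#' Write and read radiographs as 8-bit PNG with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records `plane_id`, `timestamp` and
#' `bit_depth`.
#'
#' @param rg a `radiograph` (float images are min-max quantized first).
#' @param path PNG file path.
#' @return `read_radiograph`: a `radiograph`; `write_radiograph`: the
#'   path, invisibly.
#' @export
write_radiograph <- function(rg, path) {
  q <- if (identical(rg$bit_depth, "8bit")) rg else quantize_8bit(rg)
  png::writePNG(q$pixels / 255, path)
  jsonlite::write_json(list(plane_id = rg$plane_id,
                            timestamp = rg$timestamp, bit_depth = "8bit"),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_radiograph
#' @export
read_radiograph <- function(path) {
  px <- round(png::readPNG(path) * 255)
  if (length(dim(px)) == 3) px <- px[, , 1]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE)
  else list(plane_id = NA_character_, timestamp = NA_real_)
  radiograph(px, plane_id = meta$plane_id,
             timestamp = as.numeric(meta$timestamp), bit_depth = "8bit")
}
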