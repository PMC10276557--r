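#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices with
#'   consistent outward winding.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#' @param mesh A `surface_mesh`.
#' @param t A `rigid_transform`.
#' @return The transformed `surface_mesh` (same topology).
#' @export
transform_mesh <- function(mesh, t) {
  surface_mesh(apply_transform(t, mesh$vertices), mesh$faces)
}

#' Check whether a mesh is watertight
#'
#' A closed 2-manifold has every undirected edge shared by exactly two
#' faces.
#'
#' @param mesh A `surface_mesh`.
#' @return `TRUE`/`FALSE` with attribute `open_edges` (k x 2 matrix) when
#'   not watertight.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) {
    out <- FALSE
    attr(out, "open_edges") <- matrix(integer(0), 0, 2)
    return(out)
  }
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bad <- names(tab)[tab != 2]
  if (length(bad) == 0) return(TRUE)
  out <- FALSE
  attr(out, "open_edges") <-
    matrix(as.integer(unlist(strsplit(bad, " "))), ncol = 2, byrow = TRUE)
  out
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

mesh_bbox_diag <- function(mesh) {
  r <- apply(mesh$vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}

#' Axis-aligned box mesh
#' @param size length-3 extents (mm) (scalar recycled).
#' @param center length-3 center (mm).
#' @return A watertight `surface_mesh` with 8 vertices and 12 faces.
#' @export
mesh_box <- function(size = c(10, 10, 10), center = c(0, 0, 0)) {
  size <- rep(size, length.out = 3)
  s <- size / 2
  v <- as.matrix(expand.grid(x = c(-s[1], s[1]), y = c(-s[2], s[2]),
                             z = c(-s[3], s[3])))
  v <- sweep(v, 2, center, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -s
    c(5, 6, 7), c(6, 8, 7),   # z = +s
    c(1, 2, 5), c(2, 6, 5),   # y = -s
    c(3, 7, 4), c(4, 7, 8),   # y = +s
    c(1, 5, 3), c(3, 5, 7),   # x = -s
    c(2, 4, 6), c(4, 8, 6))   # x = +s
  surface_mesh(v, f)
}

#' Latitude-longitude sphere mesh
#' @param radius sphere radius (mm).
#' @param center length-3 center (mm).
#' @param n_lat,n_lon grid resolution (latitude rows exclude the poles).
#' @return A watertight `surface_mesh`.
#' @export
mesh_sphere <- function(radius = 1, center = c(0, 0, 0), n_lat = 16,
                        n_lon = 24) {
  g <- uv_sphere_grid(n_lat, n_lon)
  v <- sweep(radius * g$all, 2, center, "+")
  surface_mesh(v, g$faces)
}

# UV sphere parameterization used by both mesh_sphere and the procedural
# bone analogs: vertex k has spherical coords (phi latitude, theta
# longitude); poles are single vertices at the start/end.
uv_sphere_grid <- function(n_lat, n_lon) {
  phi <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[2:(n_lat + 1)]
  theta <- seq(0, 2 * pi, length.out = n_lon + 1)[1:n_lon]
  g <- expand.grid(theta = theta, phi = phi)  # theta fastest
  unit <- cbind(cos(g$phi) * cos(g$theta),
                sin(g$phi),
                cos(g$phi) * sin(g$theta))
  np <- nrow(unit)
  unit <- rbind(c(0, -1, 0), unit, c(0, 1, 0))  # poles: south first
  idx <- function(i, j) 1 + (i - 1) * n_lon + ((j - 1) %% n_lon) + 1
  faces <- list()
  # south pole fan (lat ring 1)
  for (j in 1:n_lon)
    faces[[length(faces) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
  # bands
  if (n_lat > 1) {
    for (i in 1:(n_lat - 1)) for (j in 1:n_lon) {
      a <- idx(i, j); b <- idx(i, j + 1)
      c2 <- idx(i + 1, j); d <- idx(i + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a, c2, b)
      faces[[length(faces) + 1]] <- c(b, c2, d)
    }
  }
  # north pole fan
  top <- np + 2
  for (j in 1:n_lon)
    faces[[length(faces) + 1]] <- c(top, idx(n_lat, j + 1), idx(n_lat, j))
  list(all = unit,
       faces = do.call(rbind, faces),
       phi = c(-pi / 2, g$phi, pi / 2),
       theta = c(0, g$theta, 0))
}

#' Read and write meshes as ASCII PLY
#'
#' Minimal ASCII PLY 1.0 support for triangulated meshes (vertex x/y/z
#' properties and triangular face lists).
#'
#' @param path file path.
#' @return `read_ply`: a `surface_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header not terminated")
  hdr <- trimws(lines[1:end])
  fmt <- grep("^format", hdr, value = TRUE)
  if (!grepl("ascii", fmt)) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", hdr, value = TRUE)))
  body <- lines[(end + 1):length(lines)]
  vdat <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"),
                                function(x) as.numeric(x[1:3])))
  fdat <- do.call(rbind, lapply(strsplit(trimws(body[(nv + 1):(nv + nf)]),
                                         "\\s+"), function(x) {
    n <- as.integer(x[1])
    if (n != 3) stop("only triangular faces are supported")
    as.integer(x[2:4]) + 1L
  }))
  surface_mesh(vdat, fdat)
}

#' @param mesh A `surface_mesh`.
#' @rdname read_ply
#' @return `write_ply`: the path, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(format(mesh$vertices, trim = TRUE, digits = 9,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read and write meshes as ASCII STL
#' @param path file path.
#' @param mesh A `surface_mesh`.
#' @param name solid name written to the STL header.
#' @return `read_stl`: a `surface_mesh` (vertices deduplicated);
#'   `write_stl`: the path, invisibly.
#' @export
read_stl <- function(path) {
  lines <- trimws(readLines(path))
  vl <- grep("^vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  key <- apply(coords, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  ids <- match(key, key[uniq])
  verts <- coords[uniq, , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' @rdname read_stl
#' @export
write_stl <- function(mesh, path, name = "mesh") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- v[mesh$faces[i, ], , drop = FALSE]
    n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", tri[, 1], tri[, 2],
                         tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
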