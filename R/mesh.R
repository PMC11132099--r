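#' Triangle surface mesh
#'
#' Minimal container for a triangulated surface: an `n x 3` matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of 1-based vertex
#' indices per triangle. Meshes are not required to be watertight, but every
#' face index must be valid and no triangle may have zero area.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param faces integer matrix, one row per triangle (1-based indices).
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3) stop("vertices must have 3 columns")
  if (nrow(vertices) < 3 || nrow(faces) < 1) stop("mesh must have >= 3 vertices and >= 1 face")
  if (any(!is.finite(vertices))) stop("vertices must be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices))) stop("face index out of range")
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area2 <- sqrt(rowSums(cr^2))
  if (any(area2 < 1e-12)) stop("mesh contains degenerate (zero-area) triangles")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Apply a 4x4 homogeneous (or 3x3 linear) transform to a mesh
#'
#' @param mesh a `surface_mesh`.
#' @param transform 4x4 homogeneous or 3x3 linear transform matrix.
#' @return transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, transform) {
  v <- apply_transform(mesh$vertices, transform)
  f <- mesh$faces
  A <- if (all(dim(transform) == c(4, 4))) transform[1:3, 1:3] else transform
  if (det(A) < 0) f <- f[, c(1, 3, 2)]  # keep outward orientation under reflection
  surface_mesh(v, f)
}

apply_transform <- function(points, transform) {
  points <- as.matrix(points)
  if (all(dim(transform) == c(3, 3))) {
    points %*% t(transform)
  } else if (all(dim(transform) == c(4, 4))) {
    sweep(points %*% t(transform[1:3, 1:3]), 2, transform[1:3, 4], `+`)
  } else stop("transform must be 3x3 or 4x4")
}

#' Mirror a mesh about the sagittal plane
#'
#' In the local shoulder frame (+X lateral, +Y superior, +Z anterior for a
#' right shoulder) mirroring about the body's sagittal plane flips the sign of
#' the anterior coordinate, converting a left-shoulder frame into a
#' right-shoulder frame and vice versa.
#'
#' @param mesh a `surface_mesh`.
#' @return the mirrored `surface_mesh`.
#' @export
mirror_mesh <- function(mesh) {
  transform_mesh(mesh, diag(c(1, 1, -1)))
}

mirror_points <- function(points) {
  points <- as.matrix(points)
  points[, 3] <- -points[, 3]
  points
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid glenosim", con)
  tri <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
    v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
    v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(tri, con)
  writeLines("endsolid glenosim", con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Duplicated vertices are merged exactly (string identity of coordinates).
#'
#' @param path STL file path.
#' @return a `surface_mesh`.
#' @export
read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl)) stop("no vertices found; only ASCII STL is supported")
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4])))
  key <- apply(xyz, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- xyz[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY file
#'
#' @param path PLY file path.
#' @return a `surface_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop("not a PLY file")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  vb <- lines[(hend + 1):(hend + nv)]
  fb <- lines[(hend + nv + 1):(hend + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(trimws(vb), "\\s+"), function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fb), "\\s+"), function(p) as.integer(p[2:4]) + 1L))
  surface_mesh(verts, faces)
}

# grid of (nu x nv) points -> triangle faces (indices into row-major grid)
grid_faces <- function(nu, nv) {
  f <- matrix(0L, 2 * (nu - 1) * (nv - 1), 3)
  k <- 1L
  for (i in seq_len(nu - 1)) {
    for (j in seq_len(nv - 1)) {
      a <- (i - 1L) * nv + j; b <- a + 1L; cc <- a + nv; d <- cc + 1L
      f[k, ] <- c(a, b, cc); f[k + 1L, ] <- c(b, d, cc)
      k <- k + 2L
    }
  }
  f
}
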