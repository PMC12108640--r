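# Triangulated surface meshes in mm, the central geometric container.

#' Triangulated surface mesh
#'
#' @param vertices N x 3 numeric matrix of vertex positions in mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param attributes Optional named list of per-vertex attributes.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, attributes = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be N x 3")
  if (ncol(faces) != 3) stop("faces must be M x 3")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, attributes = attributes),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_areas <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh A [surface_mesh()].
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Check that every edge is shared by exactly two faces
#' @param mesh A [surface_mesh()].
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0) return(FALSE)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

mean_edge_length <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  d <- V[e[, 1], , drop = FALSE] - V[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Apply a rigid motion to a mesh
#' @param mesh A [surface_mesh()].
#' @param R 3x3 rotation matrix.
#' @param t Translation 3-vector (mm).
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  surface_mesh(sweep(mesh$vertices %*% t(R), 2, -as.numeric(t)),
               mesh$faces, mesh$attributes)
}

#' Write a mesh as ASCII PLY
#' @param mesh A [surface_mesh()].
#' @param path Output file path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.6f %.6f %.6f", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$faces - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path File path.
#' @return A [surface_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vlines <- lines[hdr_end + seq_len(nv)]
  flines <- lines[hdr_end + nv + seq_len(nf)]
  V <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x) as.integer(x[2:4]) + 1L))
  surface_mesh(V, F)
}

#' Write a mesh as binary little-endian STL
#' @param mesh A [surface_mesh()].
#' @param path Output file path.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  V <- mesh$vertices
  F <- mesh$faces
  for (i in seq_len(nrow(F))) {
    p <- V[F[i, ], , drop = FALSE]
    n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nl <- vnorm(n)
    if (nl > 0) n <- n / nl
    writeBin(as.numeric(c(n, t(p))), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}
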