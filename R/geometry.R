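# Small 3D vector helpers shared across modules.

vnorm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Oriented plane
#'
#' A plane is stored as a unit normal `n` and scalar offset `d` such that the
#' plane is the set of points `p` with `n . p = d`.
#'
#' @param normal Numeric 3-vector; normalized internally.
#' @param offset Scalar offset in mm, or alternatively `point`, a 3-point the
#'   plane must contain.
#' @param point Optional 3-point on the plane (used instead of `offset`).
#' @return An object of class `cn_plane` with fields `normal` and `offset`.
#' @export
plane <- function(normal, offset = NULL, point = NULL) {
  n <- unitize(as.numeric(normal))
  if (is.null(offset)) {
    if (is.null(point)) stop("either offset or point must be given")
    offset <- sum(n * as.numeric(point))
  }
  structure(list(normal = n, offset = as.numeric(offset)), class = "cn_plane")
}

#' Signed distance from points to a plane
#'
#' @param pl A [plane()].
#' @param pts N x 3 matrix (or 3-vector) of points in mm.
#' @return Numeric vector of signed distances (positive on the normal side).
#' @export
plane_distance <- function(pl, pts) {
  pts <- rbind3(pts)
  as.numeric(pts %*% pl$normal) - pl$offset
}

rbind3 <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3) else as.matrix(p)
}

#' In-plane orthonormal frame
#'
#' The first in-plane axis is the projection of a reference direction
#' (by default the global superior axis, +z) onto the plane; the second is
#' `normal x first`. This gives every plane a reproducible 2D
#' parameterization.
#'
#' @param pl A [plane()].
#' @param ref Reference direction to project for the first axis.
#' @param origin Optional 3-point to use as the frame origin; defaults to the
#'   point on the plane closest to the global origin.
#' @return List with `origin` (3-pt), `e1`, `e2` (in-plane unit 3-vectors).
#' @export
plane_frame <- function(pl, ref = c(0, 0, 1), origin = NULL) {
  ref <- as.numeric(ref)
  proj <- ref - sum(ref * pl$normal) * pl$normal
  if (vnorm(proj) < 1e-8) {
    ref <- c(0, 1, 0)
    proj <- ref - sum(ref * pl$normal) * pl$normal
    if (vnorm(proj) < 1e-8) {
      ref <- c(1, 0, 0)
      proj <- ref - sum(ref * pl$normal) * pl$normal
    }
  }
  e1 <- unitize(proj)
  e2 <- cross3(pl$normal, e1)
  if (is.null(origin)) origin <- pl$offset * pl$normal
  list(origin = as.numeric(origin), e1 = e1, e2 = e2)
}

# Map 3D points into a plane frame's 2D coordinates and back.
to_plane_2d <- function(frame, pts) {
  pts <- rbind3(pts)
  d <- sweep(pts, 2, frame$origin)
  cbind(as.numeric(d %*% frame$e1), as.numeric(d %*% frame$e2))
}

from_plane_2d <- function(frame, xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) xy <- matrix(xy, ncol = 2)
  t(frame$origin + t(outer(xy[, 1], frame$e1) + outer(xy[, 2], frame$e2)))
}

# Rodrigues rotation of vector v about unit axis a by angle theta.
rotate_about <- function(v, a, theta) {
  a <- unitize(a)
  v * cos(theta) + cross3(a, v) * sin(theta) + a * sum(a * v) * (1 - cos(theta))
}

# 3x3 rotation matrix about unit axis.
rotation_matrix3 <- function(axis, theta) {
  a <- unitize(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Angle between two lines (direction sign ignored), degrees.
line_angle_deg <- function(a, b) {
  ca <- abs(sum(unitize(a) * unitize(b)))
  rad2deg(acos(pmin(1, ca)))
}
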