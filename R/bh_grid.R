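# Bernard-Hertel grid construction on the lateral condylar model:
# standard-lateral projection, Blumensaat's line, the deep-shallow (D) and
# height (H) axes, the 4x4 grid and the ACL footprint point.

# Footprint fractions: t measured from the posterior margin along D,
# h from the intercondylar roof along H.
BH_FOOTPRINT_T <- 0.248
BH_FOOTPRINT_H <- 0.285

#' Standard lateral projection
#'
#' Orthographic projection along the epicondylar axis (the direction in
#' which the medial and lateral condyles overlap completely). The 2D frame
#' is right-handed with the second axis along the projected superior
#' direction.
#'
#' @param mesh Lateral condyle [surface_mesh()].
#' @param axis Unit 3-vector to project along (epicondylar axis).
#' @param superior Approximate superior direction (sets the 2D frame).
#' @param anterior Approximate anterior direction (used by [build_grid()]
#'   to orient the deep-shallow axis).
#' @return Object of class `lateral_projection` with the projected vertex
#'   cloud (`points2d`), the frame, and a `project` closure mapping 3D
#'   points to the projection plane.
#' @export
lateral_projection <- function(mesh, axis, superior = c(0, 0, 1),
                               anterior = c(0, 1, 0)) {
  axis <- unitize(axis)
  e2 <- superior - sum(superior * axis) * axis   # in-plane superior
  if (vnorm(e2) < 1e-8) stop("superior direction parallel to the axis")
  e2 <- unitize(e2)
  e1 <- cross3(e2, axis)
  origin <- colMeans(mesh$vertices)
  project <- function(pts) {
    d <- sweep(rbind3(pts), 2, origin)
    cbind(as.numeric(d %*% e1), as.numeric(d %*% e2))
  }
  back <- function(xy) {
    xy <- rbind3m(xy)
    t(origin + t(outer(xy[, 1], e1) + outer(xy[, 2], e2)))
  }
  structure(list(direction = axis, e1 = e1, e2 = e2, origin = origin,
                 anterior2d = unitize(project(origin + unitize(anterior))[1, ] -
                                        project(origin)[1, ]),
                 superior2d = c(0, 1),
                 points2d = project(mesh$vertices),
                 project = project, back_project = back),
            class = "lateral_projection")
}

rbind3m <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 2) else as.matrix(p)
}

#' Blumensaat's line from a projected notch-roof polyline
#'
#' Smooths the projected intercondylar-roof contour (moving average) and
#' parameterizes it by arc length; the grid orientation is the first
#' principal component of its points.
#'
#' @param proj A [lateral_projection()].
#' @param roof_pts Notch-roof polyline: N x 3 world points (projected
#'   internally) or N x 2 projected points.
#' @param smooth_window Moving-average window (points; 1 disables).
#' @return Object of class `blumensaat_line`: `points` (2D), `arclength`,
#'   `direction` (unit 2-vector), `length`.
#' @export
blumensaat_line <- function(proj, roof_pts, smooth_window = 5) {
  roof_pts <- as.matrix(roof_pts)
  pts <- if (ncol(roof_pts) == 3) proj$project(roof_pts) else roof_pts
  if (nrow(pts) < 2) stop("roof polyline needs at least 2 points")
  if (smooth_window > 1 && nrow(pts) > smooth_window) {
    half <- floor(smooth_window / 2)
    n <- nrow(pts)
    sm <- pts
    for (j in 1:2) {
      cs <- cumsum(c(0, pts[, j]))
      lo <- pmax(1, seq_len(n) - half)
      hi <- pmin(n, seq_len(n) + half)
      sm[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    }
    pts <- sm
  }
  s <- contour_arclengths(pts)
  if (s[length(s)] < 1e-9) stop("degenerate roof polyline")
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  # orient anteriorly
  if (sum(dir * proj$anterior2d) < 0) dir <- -dir
  structure(list(points = pts, arclength = s, direction = unitize(dir),
                 length = s[length(s)]),
            class = "blumensaat_line")
}

#' Construct the Bernard-Hertel grid
#'
#' Using Blumensaat's line as primary reference: the deep-shallow axis D(t)
#' runs parallel to it from the posterior to the anterior margin of the
#' lateral condyle silhouette; the height axis H(h) runs perpendicular,
#' from the roof to the most inferior silhouette point. Both axes are
#' divided into 4 equal cells, and the ACL femoral footprint is placed at
#' t = 24.8% from the posterior margin, h = 28.5% from the roof.
#'
#' @param proj A [lateral_projection()] of the lateral condyle.
#' @param B A [blumensaat_line()].
#' @return Object of class `bh_grid`: `origin` (posterior-roof corner, 2D),
#'   `u` (unit anterior direction along D), `w` (unit inferior direction
#'   along H), `L_D`, `L_H` (axis lengths mm), `D_axis`/`H_axis` endpoint
#'   matrices, `cells` (list of grid segments), `footprint` (2D mm),
#'   `footprint_t_h`, and `to3d` mapping grid-plane points to model space.
#' @export
build_grid <- function(proj, B) {
  u <- B$direction
  # perpendicular, oriented inferiorly (opposite the projected superior)
  w <- c(u[2], -u[1])
  if (sum(w * proj$superior2d) > 0) w <- -w
  pts <- proj$points2d
  tu <- as.numeric(pts %*% u)
  tw <- as.numeric(pts %*% w)
  b0 <- B$points[1, ]  # a point on the roof line
  L_D <- diff(range(tu))
  if (L_D < 1e-9) stop("zero-extent deep-shallow axis")
  L_H <- max(tw) - sum(b0 * w)
  if (L_H < 1e-9) stop("zero-extent height axis")
  # grid origin: posterior margin at roof height
  origin <- b0 + (min(tu) - sum(b0 * u)) * u
  fp <- origin + BH_FOOTPRINT_T * L_D * u + BH_FOOTPRINT_H * L_H * w
  cells <- list()
  for (i in 0:4) {
    f <- i / 4
    cells[[length(cells) + 1]] <- rbind(origin + f * L_D * u,
                                        origin + f * L_D * u + L_H * w)
    cells[[length(cells) + 1]] <- rbind(origin + f * L_H * w,
                                        origin + f * L_H * w + L_D * u)
  }
  structure(list(origin = origin, u = u, w = w, L_D = L_D, L_H = L_H,
                 D_axis = rbind(origin, origin + L_D * u),
                 H_axis = rbind(origin, origin + L_H * w),
                 cells = cells,
                 footprint = fp,
                 footprint_t_h = c(t = BH_FOOTPRINT_T, h = BH_FOOTPRINT_H),
                 blumensaat = B,
                 to3d = proj$back_project),
            class = "bh_grid")
}

#' @export
print.bh_grid <- function(x, ...) {
  cat(sprintf(paste0("bh_grid: D %.1f mm, H %.1f mm, footprint (t, h) = ",
                     "(%.1f%%, %.1f%%) -> (%.2f, %.2f) mm\n"),
              x$L_D, x$L_H, 100 * x$footprint_t_h[1], 100 * x$footprint_t_h[2],
              x$footprint[1], x$footprint[2]))
  invisible(x)
}

#' Normalized grid coordinates of 2D points
#'
#' @param grid A [bh_grid()].
#' @param pts 2D points (projection-plane mm).
#' @return N x 2 matrix of (t, h) fractions.
#' @export
grid_coordinates <- function(grid, pts) {
  pts <- rbind3m(pts)
  d <- sweep(pts, 2, grid$origin)
  cbind(t = as.numeric(d %*% grid$u) / grid$L_D,
        h = as.numeric(d %*% grid$w) / grid$L_H)
}

#' Write a grid as JSON
#'
#' Axes endpoints and cell lines in projection-plane mm, the footprint
#' point, and its 3D back-projection.
#'
#' @param grid A [bh_grid()].
#' @param path Output JSON path.
#' @export
write_grid_json <- function(grid, path) {
  payload <- list(
    D_axis = unname(grid$D_axis), H_axis = unname(grid$H_axis),
    L_D = grid$L_D, L_H = grid$L_H,
    cells = lapply(grid$cells, unname),
    footprint = unname(grid$footprint),
    footprint_t_h = unname(grid$footprint_t_h),
    footprint_3d = unname(as.numeric(grid$to3d(grid$footprint)[1, ])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Full grid construction for a phantom-style model
#'
#' Convenience wrapper: project the lateral mesh along the epicondylar
#' axis, build Blumensaat's line from the roof polyline, and construct the
#' grid.
#'
#' @param lateral_mesh Lateral [surface_mesh()].
#' @param axis Epicondylar axis (unit 3-vector).
#' @param roof_polyline N x 3 notch-roof points (world mm).
#' @param superior,anterior Direction conventions for the projection.
#' @return A [build_grid()] result.
#' @export
bh_grid_from_mesh <- function(lateral_mesh, axis, roof_polyline,
                              superior = c(0, 0, 1), anterior = c(0, 1, 0)) {
  proj <- lateral_projection(lateral_mesh, axis, superior, anterior)
  B <- blumensaat_line(proj, roof_polyline)
  build_grid(proj, B)
}
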