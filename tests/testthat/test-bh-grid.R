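# Lateral projection, Blumensaat's line and the Bernard-Hertel grid.

test_that("projection of an axis-aligned ellipsoid has the analytic silhouette extents", {
  r <- c(8, 6, 5); sp <- 0.5
  axs <- lapply(r, function(ri) seq(-ri - 2, ri + 2, by = sp))
  g <- expand.grid(x = axs[[1]], y = axs[[2]], z = axs[[3]])
  mask <- array((g$x / r[1])^2 + (g$y / r[2])^2 + (g$z / r[3])^2 <= 1,
                vapply(axs, length, integer(1)))
  mesh <- extract_surface(mask, sp, c(-r[1] - 2, -r[2] - 2, -r[3] - 2))
  proj <- lateral_projection(mesh, c(1, 0, 0))
  ext <- apply(proj$points2d, 2, function(v) diff(range(v)))
  expect_lt(max(abs(ext - 2 * r[2:3])), 3 * sp)
  # idempotence: projecting already-projected 3D points is the identity
  p3 <- proj$back_project(proj$points2d[1:50, ])
  expect_lt(max(abs(proj$project(p3) - proj$points2d[1:50, ])), 1e-9)
})

test_that("jointly rotating mesh and axis leaves the silhouette shape unchanged", {
  mesh <- phantom_small_mesh()
  axis <- c(1, 0, 0)
  proj1 <- lateral_projection(mesh, axis)
  R <- condylenav:::rotation_matrix3(c(0.2, 0.5, 1), 0.9)
  mesh2 <- transform_mesh(mesh, R, c(4, -2, 6))
  proj2 <- lateral_projection(mesh2, as.numeric(R %*% axis),
                              superior = as.numeric(R %*% c(0, 0, 1)),
                              anterior = as.numeric(R %*% c(0, 1, 0)))
  a <- scale(proj1$points2d, scale = FALSE)
  b <- scale(proj2$points2d, scale = FALSE)
  # Procrustes: after the optimal rotation the clouds coincide
  sv <- svd(crossprod(a, b))
  Rp <- sv$v %*% t(sv$u)
  expect_lt(max(abs(a %*% t(Rp) - b)), 1e-6)
})

test_that("Blumensaat line handles collinear input and recovers the planted roof", {
  ph <- phantom_default()
  mesh <- phantom_default_mesh()
  proj <- lateral_projection(mesh, ph$truth$epicondylar_axis)
  seg <- rbind(c(0, -10, 0), c(0, 10, 4))
  B0 <- blumensaat_line(proj, seg)
  expect_equal(unname(B0$direction),
               unname(condylenav:::unitize(proj$project(seg)[2, ] -
                                             proj$project(seg)[1, ])),
               tolerance = 1e-9)
  B <- blumensaat_line(proj, ph$truth$blumensaat_polyline)
  # planted roof direction in the projection plane
  truth_dir <- ph$truth$bh$u
  ang <- acos(min(1, abs(sum(B$direction * truth_dir)))) * 180 / pi
  expect_lt(ang, 2)
  # arc length is monotone with total equal to the polyline length
  expect_true(all(diff(B$arclength) >= 0))
  expect_equal(max(B$arclength),
               sum(sqrt(rowSums(diff(B$points)^2))), tolerance = 1e-9)
  expect_error(blumensaat_line(proj, rbind(c(0, 0, 0))), "2 points")
})

test_that("grid axes, cells and footprint follow the construction rules", {
  ph <- phantom_default()
  mesh <- phantom_default_mesh()
  pl <- plane(-ph$truth$epicondylar_axis, point = c(0, 0, 0))
  lat <- resect_medial(mesh, pl, ph$truth$lateral_marker_pt)
  g <- bh_grid_from_mesh(lat, ph$truth$epicondylar_axis,
                         ph$truth$blumensaat_polyline)
  # orthogonality is exact by construction
  expect_lt(abs(sum(g$u * g$w)), 1e-9)
  # matches the analytic phantom construction
  expect_equal(g$L_D, ph$truth$bh$L_D, tolerance = 0.02 * ph$truth$bh$L_D)
  expect_equal(g$L_H, ph$truth$bh$L_H, tolerance = 0.02 * ph$truth$bh$L_H)
  fp3 <- g$to3d(g$footprint)[1, ]
  expect_lt(sqrt(sum((fp3[2:3] - ph$truth$footprint_pt[2:3])^2)), 2)
  # normalized footprint coordinates
  expect_equal(unname(grid_coordinates(g, g$footprint)[1, ]),
               c(0.248, 0.285), tolerance = 1e-9)
})

test_that("the footprint offsets scale with the axis lengths", {
  # directly on a synthetic unit-square silhouette with a horizontal roof
  sq <- as.matrix(expand.grid(seq(0, 10, 0.25), seq(0, 8, 0.25)))
  proj <- list(points2d = sq, superior2d = c(0, 1), anterior2d = c(1, 0),
               back_project = function(xy) cbind(0, xy))
  class(proj) <- "lateral_projection"
  B <- blumensaat_line(proj, rbind(c(0, 8), c(10, 8)), smooth_window = 1)
  g <- build_grid(proj, B)
  expect_equal(g$L_D, 10, tolerance = 1e-9)
  expect_equal(g$L_H, 8, tolerance = 1e-9)
  # offsets from the posterior-roof corner: 24.8% of D and 28.5% of H
  off <- g$footprint - g$origin
  expect_equal(abs(sum(off * g$u)), 2.48, tolerance = 1e-9)
  expect_equal(abs(sum(off * g$w)), 2.28, tolerance = 1e-9)
  # 4 equal divisions per axis
  d_lines <- vapply(g$cells[seq(1, 10, 2)], function(L)
    sum((L[1, ] - g$origin) * g$u), numeric(1))
  expect_equal(sort(d_lines), seq(0, 10, 2.5), tolerance = 1e-9)
  h_lines <- vapply(g$cells[seq(2, 10, 2)], function(L)
    sum((L[1, ] - g$origin) * g$w), numeric(1))
  expect_equal(sort(h_lines), seq(0, 8, 2), tolerance = 1e-9)
})

test_that("normalized footprint is invariant to rigid motion and uniform scale", {
  ph <- phantom_default()
  mesh <- phantom_default_mesh()
  pl <- plane(-ph$truth$epicondylar_axis, point = c(0, 0, 0))
  lat <- resect_medial(mesh, pl, ph$truth$lateral_marker_pt)
  g1 <- bh_grid_from_mesh(lat, ph$truth$epicondylar_axis,
                          ph$truth$blumensaat_polyline)
  lat2 <- lat
  lat2$vertices <- lat2$vertices * 2
  g2 <- bh_grid_from_mesh(lat2, ph$truth$epicondylar_axis,
                          ph$truth$blumensaat_polyline * 2)
  expect_equal(g2$L_D, 2 * g1$L_D, tolerance = 1e-6)
  expect_equal(grid_coordinates(g2, g2$footprint),
               grid_coordinates(g1, g1$footprint), tolerance = 1e-9)
  # footprint offsets double with the silhouette
  expect_equal(unname(g2$footprint - g2$origin),
               2 * unname(g1$footprint - g1$origin), tolerance = 1e-6)
})
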