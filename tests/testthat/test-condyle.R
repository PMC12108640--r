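# Planar curvature, ellipse fitting, section objective, plane optimization
# and resection.

frame0 <- function() plane_frame(plane(c(0, 0, 1), 0))

test_that("planar curvature matches analytic circles, lines and ellipses", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- planar_contour(cbind(2 * cos(th), 2 * sin(th)), frame0(),
                         closed = TRUE)
  k <- contour_curvature(circ)
  expect_lt(max(abs(k - 0.5)), 1e-3)
  seg <- planar_contour(cbind(seq(0, 10, length.out = 50), 0.5), frame0())
  expect_lt(max(abs(contour_curvature(seg))), 1e-9)
  th2 <- seq(0, 2 * pi, length.out = 721)[-721]
  ell <- planar_contour(cbind(2 * cos(th2), sin(th2)), frame0(),
                        closed = TRUE)
  ke <- contour_curvature(ell)
  # analytic: a*b / (a^2 sin^2 t + b^2 cos^2 t)^(3/2); vertex value a/b^2 = 2
  expect_lt(abs(ke[1] - 2) / 2, 0.01)
  analytic <- 2 / (4 * sin(th2)^2 + cos(th2)^2)^1.5
  expect_lt(max(abs(ke - analytic) / analytic), 0.01)
})

test_that("curvature rejects short and stationary inputs", {
  expect_error(contour_curvature(planar_contour(cbind(1:4, 1), frame0())),
               "5")
  expect_error(planar_contour(cbind(c(0, 0), c(0, 0)), frame0(),
                              closed = TRUE), "3")
})

test_that("articular arc selection keeps the circular part and the prominence", {
  # circle: whole contour returned
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  circ <- planar_contour(cbind(cos(th), sin(th)), frame0(), closed = TRUE)
  arc <- articular_region(circ, resample_n = 0)
  expect_identical(nrow(arc$points), nrow(circ$points))
  # half circle welded to a chord: straight part excluded
  half <- seq(-pi / 2, pi / 2, length.out = 121)
  r <- 5
  chord <- cbind(0, seq(r, -r, length.out = 80)[-c(1, 80)])
  weld <- planar_contour(rbind(cbind(r * cos(half), r * sin(half)), chord),
                         frame0(), closed = TRUE)
  arc2 <- articular_region(weld)
  # arc length of selected points lying on the chord (x near 0), relative
  # to the chord's total length: at least 95% of the chord is excluded
  on_chord <- abs(arc2$points[, 1]) < 0.2
  sel_chord_len <- sum(sqrt(rowSums(diff(arc2$points)^2)) *
                         (on_chord[-1] & on_chord[-length(on_chord)]))
  expect_lt(sel_chord_len / (2 * r), 0.05)
  # ellipse: the selected arc contains the major-axis vertex
  th2 <- seq(0, 2 * pi, length.out = 241)[-241]
  ell <- planar_contour(cbind(3 * cos(th2), 1.5 * sin(th2)), frame0(),
                        closed = TRUE)
  arc3 <- articular_region(ell)
  # the arc reaches a major-axis vertex (polar angle 0 or 180 degrees)
  ang <- abs(atan2(arc3$points[, 2] / 1.5, arc3$points[, 1] / 3)) * 180 / pi
  expect_lt(min(pmin(ang, 180 - ang)), 5)
})

test_that("ellipse fitting exactly recovers noiseless conics", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  # eccentricity of a 3:2 ellipse
  f <- fit_ellipse(cbind(3 * cos(th), 2 * sin(th)))
  expect_equal(f$eccentricity, sqrt(1 - 4 / 9), tolerance = 1e-6)
  # circle
  fc <- fit_ellipse(cbind(cos(th), sin(th)))
  expect_lt(fc$eccentricity, 1e-6)
  expect_lt(max(abs(fc$center)), 1e-9)
  # grid of aspect ratios and rotations, translated off-center
  for (ab in c(1, 2, 3)) for (rot in c(0, 30, 60) * pi / 180) {
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    pts <- cbind(ab * cos(th), 1 * sin(th)) %*% t(R)
    pts <- sweep(pts, 2, c(-7, 13))
    ff <- fit_ellipse(pts)
    expect_equal(unname(ff$semi_axes), c(ab, 1), tolerance = 1e-6)
    expect_equal(unname(ff$center), c(-7, 13) * -1, tolerance = 1e-6)
    expect_lt(ff$residual_rms, 1e-8)
    # conic invariant: B^2 - 4AC < 0 and e = sqrt(1 - b^2/a^2)
    cf <- ff$coeffs
    expect_lt(cf[2]^2 - 4 * cf[1] * cf[3], 0)
  }
  expect_error(fit_ellipse(cbind(3 * cos(th[1:5]), 2 * sin(th[1:5]))), "6")
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10) + 3)), "collinear")
})

test_that("section series cuts parallel planes at the requested offsets", {
  mesh <- digitized_sphere_mesh(10, 1)
  pl <- plane(c(1, 0, 0), 0)
  secs <- section_series(mesh, pl, n = 3, spacing = 2, side = "medial")
  expect_length(secs, 3)
  offs <- vapply(secs, function(ct) attr(ct, "offset"), numeric(1))
  expect_equal(offs, c(2, 4, 6))
  expect_true(all(vapply(secs, function(ct) ct$closed, logical(1))))
  # lateral side runs the other way
  secs2 <- section_series(mesh, pl, n = 3, spacing = 2, side = "lateral")
  expect_equal(vapply(secs2, function(ct) attr(ct, "offset"), numeric(1)),
               -c(2, 4, 6))
})

test_that("ellipsoid section centers are collinear", {
  ph <- phantom_lobes()
  mesh <- phantom_lobes_mesh()
  pl <- plane(c(-1, 0, 0), 0)  # medial orientation
  secs <- section_series(mesh, pl, n = 5, spacing = 2.5, side = "lateral")
  ctrs <- t(vapply(secs, function(ct) fit_ellipse(ct$points)$center,
                   numeric(2)))
  # best-fit line residual of the in-plane centers
  pc <- prcomp(ctrs)
  expect_lt(max(abs(pc$x[, 2])), 0.5)
})

test_that("sphere sections give a near-zero objective and direct dispersion oracle holds", {
  mesh <- digitized_sphere_mesh(10, 0.5)
  pl <- plane(c(1, 0, 0), 0)
  sm <- section_series(mesh, pl, 3, 2, "medial")
  sl <- section_series(mesh, pl, 3, 2, "lateral")
  obj <- plane_objective(sm, sl)
  expect_lt(obj$mean_eccentricity, 0.05)
  expect_lt(obj$focal_dispersion, 0.5)
  # direct RMS-from-centroid oracle on the actual foci
  foci <- do.call(rbind, lapply(obj$per_section, function(f) f$foci))
  oracle <- sqrt(mean(rowSums(sweep(foci, 2, colMeans(foci))^2)))
  expect_equal(obj$focal_dispersion, oracle, tolerance = 1e-12)
})

test_that("cylinder sections get more eccentric with tilt", {
  cyl_mask <- function() {
    axs <- seq(-12, 12, by = 0.5)
    g <- expand.grid(x = axs, y = axs, z = axs)
    array(g$x^2 + g$y^2 <= 25 & abs(g$z) <= 10, rep(length(axs), 3))
  }
  mesh <- extract_surface(cyl_mask(), 0.5, rep(-12, 3))
  ecc_at <- function(tilt_deg) {
    n <- condylenav:::rotate_about(c(0, 0, 1), c(1, 0, 0),
                                   condylenav:::deg2rad(tilt_deg))
    pl <- plane(n, 0)
    secs <- section_series(mesh, pl, 3, 1.5, "medial")
    plane_objective(secs, list(), use_arc = FALSE)$mean_eccentricity
  }
  expect_gt(ecc_at(30), ecc_at(10))
})

test_that("cutting-plane optimization recovers the perpendicular orientation", {
  res <- plane_recovery()
  expect_lt(res$error_deg, 1)
  expect_true(all(diff(res$trace$objective) <= 1e-12))
})

test_that("an already-optimal plane stays put", {
  ph <- phantom_lobes()
  mesh <- phantom_lobes_mesh()
  truth_n <- -ph$truth$epicondylar_axis
  cfg <- optimize_config(max_iter = 20)
  res <- optimize_cutting_plane(mesh, plane(truth_n, point = c(0, 0, 0)), cfg)
  expect_lt(condylenav:::line_angle_deg(res$plane$normal, truth_n), 1)
})

test_that("optimizer result is invariant under a joint rigid motion", {
  ph <- phantom_lobes()
  mesh <- phantom_lobes_mesh()
  truth_n <- -ph$truth$epicondylar_axis
  tilt <- condylenav:::rotate_about(truth_n, c(0, 0, 1),
                                    condylenav:::deg2rad(5))
  R <- condylenav:::rotation_matrix3(c(0.3, 1, 0.2), 0.6)
  t <- c(5, -8, 2)
  mesh2 <- transform_mesh(mesh, R, t)
  init2 <- plane(as.numeric(R %*% tilt), point = as.numeric(R %*% c(0, 0, 0)) + t)
  res2 <- optimize_cutting_plane(mesh2, init2)
  err <- condylenav:::line_angle_deg(res2$plane$normal,
                                     as.numeric(R %*% truth_n))
  expect_lt(err, 1)
})

test_that("medial resection keeps the marker side with a planar cap", {
  r <- 10
  mesh <- digitized_sphere_mesh(r, 0.5)
  pl <- plane(c(1, 0, 0), 0)
  half <- resect_medial(mesh, pl, c(5, 0, 0))
  expect_lt(abs(mesh_area(half) / (2 * pi * r^2 + pi * r^2) - 1), 0.05)
  expect_true(is_watertight(half))
  expect_gt(min(plane_distance(pl, half$vertices)), -1e-6)
  # plane that misses: unchanged
  expect_identical(resect_medial(mesh, plane(c(1, 0, 0), -15), c(0, 0, 0)),
                   mesh)
  expect_error(resect_medial(mesh, pl, c(0, 0, 0)), "plane")
})
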