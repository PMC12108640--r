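# Mesh curvature, feature points, region growing, anatomical clipping.

test_that("vertex curvature matches analytic surfaces on parametric meshes", {
  sph <- uv_sphere_mesh(5)
  cv <- vertex_curvatures(sph, radius = 0)
  relK <- abs(cv$gaussian - 1 / 25) / (1 / 25)
  expect_lt(median(relK, na.rm = TRUE), 0.1)
  expect_equal(median(cv$kappa1, na.rm = TRUE), 0.2, tolerance = 0.02)
  # flat grid interior
  g <- expand.grid(x = 0:10, y = 0:10)
  V <- cbind(g$x, g$y, 0)
  F <- NULL
  idx <- matrix(seq_len(121), 11, 11)
  for (i in 1:10) for (j in 1:10)
    F <- rbind(F, c(idx[i, j], idx[i + 1, j], idx[i, j + 1]),
               c(idx[i + 1, j], idx[i + 1, j + 1], idx[i, j + 1]))
  plane_mesh <- surface_mesh(V, F)
  cvp <- vertex_curvatures(plane_mesh, radius = 0)
  interior <- g$x > 0 & g$x < 10 & g$y > 0 & g$y < 10
  expect_lt(max(abs(cvp$gaussian[interior])), 1e-6)
  # cylinder r = 2: kappa1 ~ 0.5, kappa2 ~ 0, K ~ 0
  cyl <- cylinder_mesh(2, 10)
  cvc <- vertex_curvatures(cyl, radius = 0)
  interior_c <- cyl$vertices[, 3] > 1 & cyl$vertices[, 3] < 9
  expect_equal(median(cvc$kappa1[interior_c], na.rm = TRUE), 0.5,
               tolerance = 0.01)
  expect_lt(abs(median(cvc$kappa2[interior_c], na.rm = TRUE)), 0.01)
  # invariant: gaussian is exactly the product
  ok <- !is.na(cv$gaussian)
  expect_identical(cv$gaussian[ok], (cv$kappa1 * cv$kappa2)[ok])
})

test_that("doubling the scale halves principal curvatures and quarters K", {
  sph1 <- uv_sphere_mesh(5)
  sph2 <- uv_sphere_mesh(10)
  c1 <- vertex_curvatures(sph1, radius = 0)
  c2 <- vertex_curvatures(sph2, radius = 0)
  expect_equal(median(c1$kappa1, na.rm = TRUE) / 2,
               median(c2$kappa1, na.rm = TRUE), tolerance = 0.05 * 0.1)
  expect_equal(median(c1$gaussian, na.rm = TRUE) / 4,
               median(c2$gaussian, na.rm = TRUE), tolerance = 0.05 * 0.01)
})

test_that("feature point membership equals a direct scan and respects percentiles", {
  mesh <- phantom_small_mesh()
  cv <- vertex_curvatures(mesh)
  pf <- feature_points(cv, percentile = 90)
  tau <- attr(pf, "tau")
  expect_identical(as.integer(pf),
                   which(!is.na(cv$gaussian) & cv$gaussian > tau))
  expect_identical(length(feature_points(cv, tau = max(cv$gaussian,
                                                       na.rm = TRUE))), 0L)
})

test_that("planted crease vertices are recalled by the curvature threshold", {
  ph <- phantom_default()
  mesh <- phantom_default_mesh()
  cv <- vertex_curvatures(mesh, radius = 1.5)
  near <- cn_knn_dist(ph$truth$crease_polyline, mesh$vertices) < 0.5
  pf_k <- feature_points(cv, percentile = 90, measure = "gaussian")
  in_k <- logical(length(cv$gaussian)); in_k[pf_k] <- TRUE
  expect_gte(mean(in_k[near]), 0.8)
  pf_1 <- feature_points(cv, percentile = 90, measure = "max_principal")
  in_1 <- logical(length(cv$kappa1)); in_1[pf_1] <- TRUE
  expect_gte(mean(in_1[near]), 0.95)
})

test_that("growth connects the planted crease into one dominant curve", {
  rec <- clr_recovery()
  expect_gte(rec$coverage, 0.9)
  expect_lt(rec$mean_dist, 1)
  expect_lt(rec$hausdorff, 2 * rec$mean_edge)
  expect_gte(rec$curve_len, 0.9 * rec$truth_len)
})

test_that("growth is deterministic and respects the length-3 rule", {
  mesh <- phantom_crease_mesh()
  cv <- vertex_curvatures(mesh, radius = 1.5)
  pf <- feature_points(cv, percentile = 99, measure = "max_principal")
  c1 <- grow_curves(mesh, cv, pf)
  c2 <- grow_curves(mesh, cv, pf)
  expect_identical(c1, c2)
  expect_true(all(vapply(c1, function(s) nrow(s$points) >= 3, logical(1))))
  # no repeated vertices within a curve
  expect_true(all(vapply(c1, function(s)
    !anyDuplicated(s$vertex_ids), logical(1))))
})

test_that("two well-separated ridges give two curves", {
  # construct two straight synthetic ridges as feature points directly
  mesh <- cylinder_mesh(2, 30, nth = 60, nz = 120)
  cv <- vertex_curvatures(mesh, radius = 0)
  # take two bands of vertices along z on opposite sides
  ang <- atan2(mesh$vertices[, 2], mesh$vertices[, 1])
  band1 <- which(abs(ang) < 0.06)
  band2 <- which(abs(abs(ang) - pi) < 0.06)
  pf <- c(band1, band2)
  attr(pf, "measure") <- "max_principal"
  cfg <- grow_config(eps = 1, sigma_k = Inf, theta_max = 45)
  curves <- grow_curves(mesh, cv, pf, cfg)
  long <- Filter(function(s) nrow(s$points) > 10, curves)
  expect_length(long, 2)
})

test_that("clipping splits curves at the box boundary and labels by position", {
  reg <- anatomical_region(c(0, 0, 0), diag(3), c(-5, -5, -5), c(5, 5, 5))
  # fully inside
  inside <- structure(list(vertex_ids = 1:5,
                           points = cbind(seq(-4, 4, length.out = 5), 0, 0),
                           label = "unlabeled"), class = "feature_curve")
  out <- clip_to_region(list(inside), reg)
  expect_length(out, 1)
  expect_identical(nrow(out[[1]]$points), 5L)
  # straight curve crossing one face: split point matches per-point membership
  crossing <- structure(list(vertex_ids = 1:21,
                             points = cbind(seq(-10, 10, length.out = 21), 0, 0),
                             label = "unlabeled"), class = "feature_curve")
  out2 <- clip_to_region(list(crossing), reg)
  kept <- out2[[1]]$points[, 1]
  oracle <- crossing$points[abs(crossing$points[, 1]) <= 5, 1]
  expect_identical(kept, oracle)
  # labelling: posterior (low y) -> CLR, anterior -> anterior_margin
  post <- structure(list(vertex_ids = 1:5,
                         points = cbind(seq(-4, 4, length.out = 5), -4, 0),
                         label = "unlabeled"), class = "feature_curve")
  ant <- structure(list(vertex_ids = 1:5,
                        points = cbind(seq(-4, 4, length.out = 5), 4, 0),
                        label = "unlabeled"), class = "feature_curve")
  out3 <- clip_to_region(list(post, ant), reg)
  labs <- vapply(out3, function(s) s$label, character(1))
  ys <- vapply(out3, function(s) mean(s$points[, 2]), numeric(1))
  expect_identical(labs[which.min(ys)], "CLR")
  expect_identical(labs[which.max(ys)], "anterior_margin")
  # nothing intersecting: empty result with a warning
  far <- structure(list(vertex_ids = 1:5,
                        points = cbind(100 + (1:5), 0, 0),
                        label = "unlabeled"), class = "feature_curve")
  expect_warning(out4 <- clip_to_region(list(far), reg), "region")
  expect_length(out4, 0)
})

test_that("the extracted CLR lands on the planted crease of the full phantom", {
  ph <- phantom_default()
  mesh <- phantom_default_mesh()
  pl <- plane(-ph$truth$epicondylar_axis, point = c(0, 0, 0))
  lat <- resect_medial(mesh, pl, ph$truth$lateral_marker_pt)
  curves <- extract_clr(lat, pl,
                        superior_limit = ph$truth$notch_posterior_pt)
  labs <- vapply(curves, function(s) s$label, character(1))
  expect_true("CLR" %in% labs)
  clr <- curves[[which(labs == "CLR")[1]]]
  d <- cn_knn_dist(ph$truth$crease_polyline, clr$points)
  expect_lt(mean(d), 1)
  # centroid of the labelled curve sits on the planted crease
  centroid_d <- cn_knn_dist(ph$truth$crease_polyline,
                            matrix(colMeans(clr$points), 1))
  expect_lt(centroid_d, 3)
})

test_that("growth output is invariant under rigid motion", {
  mesh <- phantom_crease_mesh()
  cv <- vertex_curvatures(mesh, radius = 1.5)
  pf <- feature_points(cv, percentile = 99, measure = "max_principal")
  c1 <- grow_curves(mesh, cv, pf)
  R <- condylenav:::rotation_matrix3(c(1, 0.5, 0.25), 0.8)
  t <- c(10, -5, 3)
  mesh2 <- transform_mesh(mesh, R, t)
  cv2 <- vertex_curvatures(mesh2, radius = 1.5)
  pf2 <- feature_points(cv2, percentile = 99, measure = "max_principal")
  c2 <- grow_curves(mesh2, cv2, pf2)
  # allow a handful of borderline threshold flips at the set boundary
  n1 <- sum(vapply(c1, function(s) nrow(s$points), integer(1)))
  n2 <- sum(vapply(c2, function(s) nrow(s$points), integer(1)))
  expect_lt(abs(n1 - n2) / n1, 0.05)
  # the dominant (crease) curve is recovered in both frames
  best1 <- c1[[which.max(vapply(c1, curve_len_helper, numeric(1)))]]
  best2 <- c2[[which.max(vapply(c2, curve_len_helper, numeric(1)))]]
  expect_lt(abs(curve_len_helper(best1) - curve_len_helper(best2)) /
              curve_len_helper(best1), 0.05)
})

test_that("curve JSON export is readable and labelled", {
  rec <- clr_recovery()
  path <- withr::local_tempfile(fileext = ".json")
  write_curves_json(list(rec$curve), path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(back, 1)
  expect_identical(length(back[[1]]$points_mm), nrow(rec$curve$points))
})
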