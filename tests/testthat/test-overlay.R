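# Frame registration, grid projection, overlay rendering and tracking.

test_that("a rendered frame registers to its own model curves within 1 mm", {
  sc <- rendered_scene()
  reg <- register_frame(sc$frame$image, sc$model_curves, calib = sc$calib)
  expect_identical(reg$status, "ok")
  cp <- sc$frame$projected_crease
  moved <- apply_rigid2d(reg$transform, cp)
  expect_lt(mean(sqrt(rowSums((moved - cp)^2))) * sc$calib, 1)
})

test_that("a shifted frame yields the shift, and featureless frames fail gracefully", {
  sc <- rendered_scene()
  # crop-based shift: identical content, offset by (10, 5) px
  big <- sc$frame$image
  crop1 <- big[16:225, 16:305]
  crop2 <- big[11:220, 6:295]   # same content appears 10 px right, 5 px down
  mc <- lapply(sc$model_curves, function(cv) sweep(cv / sc$calib,
                                                   2, c(15, 15)) * sc$calib)
  r1 <- register_frame(crop1, mc, calib = sc$calib)
  r2 <- register_frame(crop2, mc, calib = sc$calib)
  expect_identical(r1$status, "ok")
  expect_identical(r2$status, "ok")
  delta <- r2$transform$t - r1$transform$t
  ang1 <- atan2(r1$transform$R[2, 1], r1$transform$R[1, 1])
  ang2 <- atan2(r2$transform$R[2, 1], r2$transform$R[1, 1])
  expect_lt(abs(ang1 - ang2) * 180 / pi, 1)
  expect_lt(max(abs(delta - c(10, 5))), 1)
  # featureless frame: failure status, not a crash
  r3 <- register_frame(matrix(0.5, 240, 320), sc$model_curves,
                       calib = sc$calib)
  expect_identical(r3$status, "failed")
})

test_that("grid projection maps lines rigidly and preserves equal divisions", {
  ph <- phantom_default()
  mesh <- phantom_default_mesh()
  pl <- plane(-ph$truth$epicondylar_axis, point = c(0, 0, 0))
  lat <- resect_medial(mesh, pl, ph$truth$lateral_marker_pt)
  grid <- bh_grid_from_mesh(lat, ph$truth$epicondylar_axis,
                            ph$truth$blumensaat_polyline)
  # identity transform, unit calibration: pixel coords equal mm coords
  pg <- project_grid(grid, rigid_transform2d(), calib = 1)
  expect_equal(pg$footprint, unname(grid$footprint), tolerance = 1e-12)
  # pure translation moves every point by exactly that amount
  tf <- rigid_transform2d(t = c(10, 5))
  pg2 <- project_grid(grid, tf, calib = 1)
  expect_equal(pg2$footprint, unname(grid$footprint) + c(10, 5),
               tolerance = 1e-12)
  for (i in seq_along(pg$cells))
    expect_equal(pg2$cells[[i]], sweep(pg$cells[[i]], 2, -c(10, 5)),
                 tolerance = 1e-12)
  # equal divisions survive a rigid map: consecutive D-line spacings equal
  tf3 <- rigid_from_angle(25, c(3, -2))
  pg3 <- project_grid(grid, tf3, calib = 1)
  d_starts <- t(vapply(pg3$cells[seq(1, 10, 2)], function(L) L[1, ],
                       numeric(2)))
  gaps <- sqrt(rowSums(diff(d_starts)^2))
  expect_lt(max(abs(gaps - mean(gaps))), 1e-9)
  # fully out-of-frame projection warns
  far <- rigid_transform2d(t = c(1e5, 1e5))
  expect_warning(project_grid(grid, far, calib = 1,
                              frame_size = c(240, 320)), "outside")
})

test_that("overlay blending is exact on line pixels and bit-exact elsewhere", {
  frame <- matrix(0.5, 60, 80)
  lines <- list(cells = list(cbind(c(10, 50), c(20, 20))),
                boundary = list(), footprint = NULL)
  spec <- overlay_spec(alpha = 0.4, grid_color = c(1, 1, 1))
  out <- render_overlay(frame, lines, spec)
  px <- condylenav:::rasterize_polylines(lines$cells, 80, 60)
  expect_equal(unique(out[px]), 0.5 * 0.6 + 0.4 * 1, tolerance = 1e-12)
  untouched <- matrix(TRUE, 60, 80)
  untouched[px] <- FALSE
  expect_identical(out[untouched], frame[untouched])
  # alpha 0 leaves the frame untouched; alpha 1 paints pure color
  out0 <- render_overlay(frame, lines, overlay_spec(alpha = 0))
  expect_identical(out0, frame)
  out1 <- render_overlay(frame, lines, overlay_spec(alpha = 1,
                                                    grid_color = c(1, 1, 1)))
  expect_equal(unique(out1[px]), 1, tolerance = 1e-12)
})

test_that("tracking a static sequence is a fixed point", {
  sc <- rendered_scene()
  frames <- list(sc$frame$image, sc$frame$image, sc$frame$image)
  tr <- track_frames(frames, sc$model_curves, calib = sc$calib)
  expect_true(all(tr$log$status == "ok"))
  for (i in 2:3) {
    expect_equal(tr$transforms[[i]]$R, tr$transforms[[1]]$R,
                 tolerance = 1e-9)
    expect_equal(tr$transforms[[i]]$t, tr$transforms[[1]]$t,
                 tolerance = 1e-9)
  }
  expect_false(any(tr$log$reinit[-1]))
})

test_that("tracking follows a panning camera and recovers from a dropout", {
  sc <- rendered_scene()
  ph <- sc$phantom
  ctr <- colMeans(ph$truth$crease_polyline)
  frames <- list()
  truth_px <- list()
  for (i in 0:5) {
    cam <- look_at_camera(eye = ctr + c(-45, -45, -45) + c(0, i * 0.4, 0),
                          target = ctr + c(0, i * 0.4, 0),
                          fx = 200, fy = 200, width = 320, height = 240)
    fr <- render_arthro_frame(sc$mesh, cam, ph$truth)
    frames[[i + 1]] <- fr$image
    truth_px[[i + 1]] <- fr$projected_crease
  }
  tr <- track_frames(frames, sc$model_curves, calib = sc$calib)
  expect_true(all(tr$log$status == "ok"))
  # per-frame overlay error vs the ground-truth projection
  for (i in seq_along(frames)) {
    moved <- apply_rigid2d(tr$transforms[[i]],
                           sc$frame$projected_crease)
    d <- cn_knn_dist(truth_px[[i]], moved)
    expect_lt(mean(d), 2)
  }
  # blank middle frame: marked failed, tracking recovers afterwards
  frames2 <- frames[1:4]
  frames2[[3]] <- matrix(0.5, 240, 320)
  tr2 <- track_frames(frames2, sc$model_curves, calib = sc$calib)
  expect_identical(tr2$log$status, c("ok", "ok", "failed", "ok"))
  expect_true(tr2$log$reinit[4])
})
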