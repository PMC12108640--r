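# Shared fixtures, generated in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# --- meshes -----------------------------------------------------------------

# parametric UV sphere with outward-oriented faces
uv_sphere_mesh <- function(r = 5, nth = 60, nph = 120) {
  th <- seq(0, pi, length.out = nth)
  ph <- seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)]
  V <- rbind(c(0, 0, r))
  idx <- matrix(0L, nth, nph)
  idx[1, ] <- 1L
  for (i in 2:(nth - 1)) {
    for (j in seq_len(nph)) {
      V <- rbind(V, r * c(sin(th[i]) * cos(ph[j]), sin(th[i]) * sin(ph[j]),
                          cos(th[i])))
      idx[i, j] <- nrow(V)
    }
  }
  V <- rbind(V, c(0, 0, -r))
  idx[nth, ] <- nrow(V)
  F <- NULL
  for (i in seq_len(nth - 1)) for (j in seq_len(nph)) {
    jn <- j %% nph + 1
    a <- idx[i, j]; b <- idx[i, jn]; cc <- idx[i + 1, j]; d <- idx[i + 1, jn]
    if (i == 1) F <- rbind(F, c(a, d, cc))
    else if (i == nth - 1) F <- rbind(F, c(a, b, cc))
    else F <- rbind(F, c(a, b, cc), c(b, d, cc))
  }
  m <- surface_mesh(V, F)
  # orient outward (positive enclosed volume)
  vol <- sum(vapply(seq_len(nrow(F)), function(f) {
    p <- V[F[f, ], ]
    det(p) / 6
  }, numeric(1)))
  if (vol < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# open parametric cylinder along z
cylinder_mesh <- function(r = 2, len = 10, nth = 100, nz = 40) {
  ph <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  zs <- seq(0, len, length.out = nz)
  g <- expand.grid(ph = ph, z = zs)
  V <- cbind(r * cos(g$ph), r * sin(g$ph), g$z)
  idx <- matrix(seq_len(nth * nz), nth, nz)
  F <- NULL
  for (i in seq_len(nth)) for (j in seq_len(nz - 1)) {
    inx <- i %% nth + 1
    F <- rbind(F, c(idx[i, j], idx[inx, j], idx[i, j + 1]),
               c(idx[inx, j], idx[inx, j + 1], idx[i, j + 1]))
  }
  surface_mesh(V, F)
}

# digitized solid sphere mask
sphere_mask <- function(r = 10, spacing = 0.5, margin = 3) {
  axs <- seq(-r - margin, r + margin, by = spacing)
  n <- length(axs)
  g <- expand.grid(x = axs, y = axs, z = axs)
  mask <- array(g$x^2 + g$y^2 + g$z^2 <= r^2, c(n, n, n))
  list(mask = mask, spacing = spacing, origin = rep(-r - margin, 3))
}

digitized_sphere_mesh <- function(r = 10, spacing = 0.5) {
  sm <- sphere_mask(r, spacing)
  extract_surface(sm$mask, sm$spacing, sm$origin)
}

# --- phantoms ---------------------------------------------------------------

phantom_small <- function() fixture("phantom_small",
  make_femur_phantom(phantom_spec(voxel_spacing = 1, seed = 11)))

phantom_small_mesh <- function() fixture("phantom_small_mesh",
  phantom_mesh(phantom_small()))

# lobes only: prolate ellipsoids for the plane-recovery properties
phantom_lobes <- function() fixture("phantom_lobes",
  make_femur_phantom(phantom_spec(voxel_spacing = 1, noise_sd = 0, seed = 4,
                                  include_bridge = FALSE,
                                  include_shaft = FALSE,
                                  include_crease = FALSE)))

phantom_lobes_mesh <- function() fixture("phantom_lobes_mesh",
  phantom_mesh(phantom_lobes()))

# high-resolution single-crease phantom for CLR recovery
phantom_crease <- function() fixture("phantom_crease",
  make_femur_phantom(phantom_spec(seed = 7, include_bridge = FALSE,
                                  include_shaft = FALSE)))

phantom_crease_mesh <- function() fixture("phantom_crease_mesh",
  phantom_mesh(phantom_crease()))

# default full phantom at CT-like pitch
phantom_default <- function() fixture("phantom_default",
  make_femur_phantom(phantom_spec(seed = 5)))

phantom_default_mesh <- function() fixture("phantom_default_mesh",
  phantom_mesh(phantom_default()))

# --- cached expensive results ----------------------------------------------

# CLR recovery on the single-crease phantom (used by module + acceptance)
clr_recovery <- function() fixture("clr_recovery", {
  ph <- phantom_crease()
  mesh <- phantom_crease_mesh()
  cv <- vertex_curvatures(mesh, radius = 1.5)
  pf <- feature_points(cv, percentile = 95, measure = "max_principal")
  curves <- grow_curves(mesh, cv, pf)
  lens <- vapply(curves, function(s)
    sum(sqrt(rowSums(diff(s$points)^2))), numeric(1))
  best <- curves[[which.max(lens)]]
  truthc <- ph$truth$crease_polyline
  me <- condylenav:::mean_edge_length(mesh)
  d_curve_truth <- cn_knn_dist(truthc, best$points)
  d_truth_curve <- cn_knn_dist(best$points, truthc)
  # precision: directed Hausdorff of the extracted curve to the planted
  # crease; completeness is covered separately by `coverage`
  list(curve = best, n_curves = length(curves),
       mean_dist = mean(d_curve_truth),
       coverage = mean(d_truth_curve < 2 * me),
       hausdorff = max(d_curve_truth),
       mean_edge = me,
       truth_len = sum(sqrt(rowSums(diff(truthc)^2))),
       curve_len = lens[which.max(lens)])
})

cn_knn_dist <- function(data, query) {
  condylenav:::cn_knn(rbind(data), rbind(query), 1)$dist[, 1]
}

# cutting-plane recovery on the lobes phantom (5 deg initial tilt)
plane_recovery <- function() fixture("plane_recovery", {
  ph <- phantom_lobes()
  mesh <- phantom_lobes_mesh()
  truth_n <- -ph$truth$epicondylar_axis  # medially oriented
  tilt <- condylenav:::rotate_about(truth_n, c(0, 0, 1),
                                    condylenav:::deg2rad(5))
  res <- optimize_cutting_plane(mesh, plane(tilt, point = c(0, 0, 0)))
  res$error_deg <- condylenav:::line_angle_deg(res$plane$normal, truth_n)
  res
})

# textured random image for SIFT tests
textured_image <- function(n = 192, seed = 1) fixture(
  paste0("textured_", n, "_", seed), {
    img <- withr::with_seed(seed, matrix(runif(n * n), n, n))
    img <- condylenav:::gblur2(img, 3)
    (img - min(img)) / diff(range(img))
  })

# rendered arthroscopic-style frame of the small phantom with model curves
rendered_scene <- function() fixture("rendered_scene", {
  ph <- phantom_small()
  mesh <- phantom_small_mesh()
  ctr <- colMeans(ph$truth$crease_polyline)
  cam <- look_at_camera(eye = ctr + c(-45, -45, -45), target = ctr,
                        fx = 200, fy = 200, width = 320, height = 240)
  fr <- render_arthro_frame(mesh, cam, ph$truth)
  vis <- matrix(as.numeric(is.finite(fr$depth)), 240, 320)
  sil <- is.finite(fr$depth) &
    !(condylenav:::shift2(vis, 0, 1) > 0 & condylenav:::shift2(vis, 0, -1) > 0 &
        condylenav:::shift2(vis, 1, 0) > 0 & condylenav:::shift2(vis, -1, 0) > 0)
  calib <- 0.39
  list(phantom = ph, mesh = mesh, camera = cam, frame = fr, calib = calib,
       model_curves = list(fr$projected_crease * calib,
                           edge_points(sil) * calib))
})

face_areas_pub <- function(mesh) condylenav:::face_areas(mesh)

curve_len_helper <- function(s) sum(sqrt(rowSums(diff(s$points)^2)))

expect_rigid_close <- function(tf, angle_deg, t, tol_angle = 0.5, tol_t = 1) {
  ang <- atan2(tf$R[2, 1], tf$R[1, 1]) * 180 / pi
  expect_lt(abs(ang - angle_deg), tol_angle)
  expect_lt(max(abs(tf$t - t)), tol_t)
}
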