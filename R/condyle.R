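# Sagittal-profile geometric analysis: planar curvature, constrained
# ellipse fitting, the parallel-section eccentricity / focal-dispersion
# objective, iterative cutting-plane optimization, and virtual resection.

#' Signed curvature of a planar contour
#'
#' kappa(t) = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2), with derivatives taken
#' by centered finite differences with respect to the arc-length
#' parameterization (one-sided at open endpoints). Counter-clockwise closed
#' contours have positive curvature where convex.
#'
#' @param contour A [planar_contour()].
#' @return Numeric vector of per-point curvature (1/mm).
#' @export
contour_curvature <- function(contour) {
  pts <- contour$points
  n <- nrow(pts)
  if (n < 5) stop("need at least 5 contour points")
  closed <- contour$closed
  t0 <- contour_arclengths(pts, closed = FALSE)
  if (closed) {
    # wrap one point on each side
    last_seg <- vnorm(pts[1, ] - pts[n, ])
    ptsx <- rbind(pts[n, ], pts, pts[1, ])
    tt <- c(t0[1] - last_seg, t0, t0[n] + last_seg)
  } else {
    ptsx <- rbind(2 * pts[1, ] - pts[2, ], pts, 2 * pts[n, ] - pts[n - 1, ])
    tt <- c(2 * t0[1] - t0[2], t0, 2 * t0[n] - t0[n - 1])
  }
  i <- seq_len(n) + 1L
  h1 <- tt[i] - tt[i - 1]
  h2 <- tt[i + 1] - tt[i]
  if (any(h1 <= 0) || any(h2 <= 0)) stop("stationary points on contour")
  d1 <- function(f) (f[i + 1] * h1^2 - f[i - 1] * h2^2 + f[i] * (h2^2 - h1^2)) /
    (h1 * h2 * (h1 + h2))
  d2 <- function(f) 2 * (f[i - 1] * h2 + f[i + 1] * h1 - f[i] * (h1 + h2)) /
    (h1 * h2 * (h1 + h2))
  xp <- d1(ptsx[, 1]); yp <- d1(ptsx[, 2])
  xpp <- d2(ptsx[, 1]); ypp <- d2(ptsx[, 2])
  sp2 <- xp^2 + yp^2
  if (any(sp2 < 1e-20)) stop("stationary points on contour")
  (xp * ypp - yp * xpp) / sp2^1.5
}

# circular index helper
circ_idx <- function(i, n) ((i - 1L) %% n) + 1L

# Uniform arc-length resampling of a polyline / polygon.
resample_contour <- function(pts, n_out, closed = FALSE) {
  if (closed) pts <- rbind(pts, pts[1, ])
  tt <- contour_arclengths(pts)
  L <- tt[length(tt)]
  s <- if (closed) seq(0, L, length.out = n_out + 1)[-(n_out + 1)]
  else seq(0, L, length.out = n_out)
  cbind(approx(tt, pts[, 1], xout = s, ties = "ordered")$y,
        approx(tt, pts[, 2], xout = s, ties = "ordered")$y)
}

# Circular moving-average smoothing of closed-contour points.
smooth_closed <- function(pts, window = 5) {
  n <- nrow(pts)
  half <- floor(window / 2)
  out <- pts
  for (j in 1:2) {
    acc <- rep(0, n)
    for (q in -half:half) acc <- acc + pts[circ_idx(seq_len(n) + q, n), j]
    out[, j] <- acc / (2 * half + 1)
  }
  out
}

#' Articular-arc selection on a condylar contour
#'
#' Returns the contiguous subarc of low curvature variance around the
#' prominent (maximum-curvature) portion of a closed sagittal contour - the
#' near-circular articular arc used for ellipse fitting. A sliding window
#' of the given arc-length fraction is scored by curvature variance; the
#' best window containing the prominence is then extended while the
#' curvature stays consistent with the window median.
#'
#' Contours coming straight from an iso-surfaced mesh carry sub-voxel
#' jitter that dominates finite-difference curvature, so the contour is
#' first resampled at uniform arc length and smoothed by a circular moving
#' average; selection happens on the preprocessed polygon.
#'
#' @param contour Closed [planar_contour()].
#' @param curvature Optional precomputed curvature for the (resampled)
#'   contour; when supplied, `resample_n = 0` must be used.
#' @param window_frac Window size as a fraction of total arc length.
#' @param resample_n Number of uniform resampling points (0 disables
#'   preprocessing and uses the raw contour points).
#' @param smooth_window Moving-average window (points) after resampling.
#' @return An open [planar_contour()] subarc (or the preprocessed closed
#'   contour when the curvature is globally uniform). The selected indices
#'   (into the preprocessed contour) are attached as attribute `indices`.
#' @export
articular_region <- function(contour, curvature = NULL, window_frac = 0.4,
                             resample_n = 200, smooth_window = 7) {
  if (!contour$closed) stop("articular_region expects a closed contour")
  if (resample_n > 0) {
    pts <- resample_contour(contour$points, resample_n, closed = TRUE)
    pts <- smooth_closed(pts, smooth_window)
    contour <- planar_contour(pts, contour$frame, closed = TRUE)
  }
  if (is.null(curvature)) curvature <- contour_curvature(contour)
  k <- curvature
  n <- length(k)
  # light median smoothing for robustness to single-vertex spikes
  ks <- vapply(seq_len(n), function(i)
    median(k[circ_idx(i + (-2:2), n)]), numeric(1))
  rng <- max(ks) - min(ks)
  if (rng < 0.05 * max(abs(ks))) return(contour)  # uniform: whole contour
  tt <- contour_arclengths(contour$points, closed = TRUE)
  L <- tt[n + 1]
  w <- window_frac * L
  prom <- which.max(ks)
  # member indices of the window centered at i (circular arc distance)
  win_members <- function(i) {
    dt <- abs(tt[seq_len(n)] - tt[i])
    dt <- pmin(dt, L - dt)
    which(dt <= w / 2)
  }
  centers <- seq_len(n)
  best <- NULL
  best_var <- Inf
  for (i in centers) {
    m <- win_members(i)
    if (!(prom %in% m)) next
    v <- var(ks[m])
    if (v < best_var) { best_var <- v; best <- i }
  }
  if (is.null(best)) { best <- prom }
  m <- win_members(best)
  # contiguous circular range around best, widened to keep the prominence
  # (its anchor) inside despite rounding
  half <- max(1L, floor((length(m) - 1) / 2))
  lo <- best - half
  hi <- best + half
  fwd <- (prom - best) %% n          # circular offsets of the prominence
  bwd <- (best - prom) %% n
  if (fwd <= bwd) hi <- max(hi, best + fwd) else lo <- min(lo, best - bwd)
  med <- median(ks[circ_idx(lo:hi, n)])
  tol <- max(5 * mad(ks[circ_idx(lo:hi, n)]), 0.15 * abs(med), 1e-12)
  repeat {
    grew <- FALSE
    if (hi - lo + 1 < n && abs(ks[circ_idx(lo - 1L, n)] - med) <= tol) {
      lo <- lo - 1L; grew <- TRUE
    }
    if (hi - lo + 1 < n && abs(ks[circ_idx(hi + 1L, n)] - med) <= tol) {
      hi <- hi + 1L; grew <- TRUE
    }
    if (!grew || hi - lo + 1 >= n) break
  }
  idx <- circ_idx(lo:hi, n)
  out <- planar_contour(contour$points[idx, , drop = FALSE], contour$frame,
                        closed = FALSE)
  attr(out, "indices") <- idx
  out
}

#' Direct constrained least-squares ellipse fit
#'
#' Fits the general conic A x^2 + B xy + C y^2 + D x + E y + F = 0 to the
#' points under the ellipse constraint B^2 - 4AC < 0, using the
#' numerically stable partitioned eigen-solve of the direct least-squares
#' formulation on centered/scaled coordinates.
#'
#' @param points N x 2 matrix (mm), N >= 6, not collinear.
#' @return Object of class `ellipse_fit`: `coeffs` (A..F), `center`,
#'   `semi_axes` (a >= b), `foci` (2 x 2 matrix), `eccentricity`,
#'   `residual_rms` (mm, gradient-normalized algebraic distance).
#' @export
fit_ellipse <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 6) stop("need at least 6 points for an ellipse fit")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)$d
  if (sv[2] < 1e-10 * max(sv[1], 1e-300)) stop("points are collinear")
  s <- sqrt(mean(rowSums(Pc^2)) / 2)
  X <- Pc[, 1] / s
  Y <- Pc[, 2] / s
  D1 <- cbind(X^2, X * Y, Y^2)
  D2 <- cbind(X, Y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no elliptical solution (degenerate input)")
  a1 <- evec[, ok[1]]
  a2 <- as.numeric(Tm %*% a1)
  p <- c(a1, a2)  # conic in normalized coordinates
  # map back: x = (u - mx), scaled by s
  Ap <- p[1]; Bp <- p[2]; Cp <- p[3]; Dp <- p[4]; Ep <- p[5]; Fp <- p[6]
  mx <- ctr[1]; my <- ctr[2]
  A <- Ap / s^2
  B <- Bp / s^2
  C <- Cp / s^2
  D <- -(2 * Ap * mx + Bp * my) / s^2 + Dp / s
  E <- -(Bp * mx + 2 * Cp * my) / s^2 + Ep / s
  Ff <- (Ap * mx^2 + Bp * mx * my + Cp * my^2) / s^2 - (Dp * mx + Ep * my) / s + Fp
  coeffs <- c(A = A, B = B, C = C, D = D, E = E, F = Ff)
  geo <- conic_to_ellipse(coeffs)
  # gradient-normalized algebraic distances
  q <- A * P[, 1]^2 + B * P[, 1] * P[, 2] + C * P[, 2]^2 + D * P[, 1] +
    E * P[, 2] + Ff
  gx <- 2 * A * P[, 1] + B * P[, 2] + D
  gy <- B * P[, 1] + 2 * C * P[, 2] + E
  res <- abs(q) / pmax(sqrt(gx^2 + gy^2), 1e-12)
  structure(c(list(coeffs = coeffs, residual_rms = sqrt(mean(res^2))), geo),
            class = "ellipse_fit")
}

# Ellipse geometry (center, axes, foci, eccentricity) from conic coefficients.
conic_to_ellipse <- function(cf) {
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; Ff <- cf[6]
  if (B^2 - 4 * A * C >= 0) stop("conic is not an ellipse")
  ctr <- solve(matrix(c(2 * A, B, B, 2 * C), 2, 2), c(-D, -E))
  F0 <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 + D * ctr[1] +
    E * ctr[2] + Ff
  M <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  lam <- ev$values
  if (any(-F0 / lam <= 0)) stop("conic is not a real ellipse")
  ax <- sqrt(-F0 / lam)
  ord <- order(ax, decreasing = TRUE)
  a <- ax[ord[1]]; b <- ax[ord[2]]
  major_dir <- ev$vectors[, ord[1]]
  cfoc <- sqrt(max(0, a^2 - b^2))
  foci <- rbind(ctr + cfoc * major_dir, ctr - cfoc * major_dir)
  list(center = ctr, semi_axes = c(a = a, b = b), foci = foci,
       major_dir = major_dir, eccentricity = sqrt(1 - b^2 / a^2))
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse_fit: center (%.3f, %.3f), a %.3f, b %.3f, e %.4f, rms %.2g\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$eccentricity, x$residual_rms))
  invisible(x)
}

#' Parallel section series through a condyle
#'
#' Cuts the mesh with `n` planes parallel to the base plane, offset along
#' its oriented normal into the requested condyle (the base-plane normal
#' points medially by convention), and keeps the largest contour per plane.
#' All section frames share the base plane's in-plane axes, so 2D
#' coordinates are directly comparable across sections (equivalent to
#' projecting onto a common plane parallel to the sections).
#'
#' @param mesh A [surface_mesh()].
#' @param pl Base [plane()] with medially-oriented normal.
#' @param n Number of sections.
#' @param spacing Distance between consecutive sections (mm).
#' @param side `"medial"` or `"lateral"`.
#' @param start_offset Offset of the first section from the base plane
#'   (default `spacing`).
#' @return List of closed [planar_contour()]s (one per plane that actually
#'   intersects; the `offset` attribute records the plane offset, and the
#'   `missing` attribute on the list names skipped planes).
#' @export
section_series <- function(mesh, pl, n = 5, spacing = 3,
                           side = c("medial", "lateral"),
                           start_offset = NULL) {
  side <- match.arg(side)
  if (n < 1) stop("n must be >= 1")
  if (is.null(start_offset)) start_offset <- spacing
  sgn <- if (side == "medial") 1 else -1
  base_frame <- plane_frame(pl)
  out <- list()
  missing <- integer(0)
  for (i in seq_len(n)) {
    off <- sgn * (start_offset + (i - 1) * spacing)
    pli <- plane(pl$normal, pl$offset + off)
    frame_i <- list(origin = base_frame$origin + off * pl$normal,
                    e1 = base_frame$e1, e2 = base_frame$e2)
    cts <- plane_mesh_contour(mesh, pli, frame_i)
    cts <- Filter(function(ct) ct$closed, cts)
    if (length(cts) == 0) { missing <- c(missing, i); next }
    ct <- cts[[1]]
    attr(ct, "offset") <- off
    out[[length(out) + 1]] <- ct
  }
  attr(out, "missing") <- missing
  out
}

#' Eccentricity and focal-dispersion objective of a section set
#'
#' Fits ellipses to the articular arcs of each sectional contour.
#' `mean_eccentricity` is the mean over fits; `focal_dispersion` is the RMS
#' distance of all foci from their common centroid after projection onto a
#' plane parallel to the sections (the shared in-plane frame). When the
#' cutting direction is perpendicular to the condylar axis the sections are
#' circular and the foci coincide, so both terms vanish.
#'
#' @param sections_medial,sections_lateral Lists of closed
#'   [planar_contour()]s in a shared in-plane frame (see [section_series()]).
#' @param lambda Weight of the dispersion term in `objective`.
#' @param span Normalizing length (mm) for the dispersion term (e.g. the
#'   condylar span along the plane normal); default is the spread of
#'   section offsets (1 if unavailable).
#' @param use_arc Fit on the [articular_region()] arc (default) or on the
#'   full contour.
#' @return List with `mean_eccentricity`, `focal_dispersion`, `objective`,
#'   `per_section` (list of [fit_ellipse()] results) and `n_fits`.
#' @export
plane_objective <- function(sections_medial, sections_lateral, lambda = 1,
                            span = NULL, use_arc = TRUE) {
  secs <- c(sections_medial, sections_lateral)
  if (length(secs) == 0) stop("no sections supplied")
  fits <- list()
  for (ct in secs) {
    fit <- tryCatch({
      src <- if (use_arc && ct$closed) {
        tryCatch(articular_region(ct), error = function(e) ct)
      } else ct
      fit_ellipse(src$points)
    }, error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
  }
  if (length(fits) == 0) stop("no section could be fitted with an ellipse")
  ecc <- vapply(fits, function(f) f$eccentricity, numeric(1))
  foci <- do.call(rbind, lapply(fits, function(f) f$foci))
  ctr <- colMeans(foci)
  disp <- sqrt(mean(rowSums(sweep(foci, 2, ctr)^2)))
  if (is.null(span)) {
    offs <- vapply(secs, function(ct) {
      o <- attr(ct, "offset")
      if (is.null(o)) NA_real_ else o
    }, numeric(1))
    span <- if (all(is.na(offs))) 1 else max(1e-6, diff(range(offs, na.rm = TRUE)))
  }
  list(mean_eccentricity = mean(ecc), focal_dispersion = disp,
       objective = mean(ecc) + lambda * disp / span,
       per_section = fits, n_fits = length(fits))
}

#' Optimizer configuration for the cutting plane
#'
#' @param n_sections_per_condyle Sections per condyle.
#' @param section_spacing Spacing between sections (mm).
#' @param angle_step_init Initial angular step (degrees).
#' @param tol Objective-change convergence threshold.
#' @param max_iter Maximum accepted-step count.
#' @param weight_lambda Dispersion weight in the scalar objective.
#' @param min_step_deg Terminal angular step (degrees).
#' @param start_offset First-section offset (mm; default `section_spacing`).
#' @export
optimize_config <- function(n_sections_per_condyle = 5, section_spacing = 3,
                            angle_step_init = 2, tol = 1e-4, max_iter = 50,
                            weight_lambda = 1, min_step_deg = 0.05,
                            start_offset = NULL) {
  stopifnot(n_sections_per_condyle >= 1, section_spacing > 0,
            angle_step_init > 0, max_iter >= 1)
  list(n_sections_per_condyle = n_sections_per_condyle,
       section_spacing = section_spacing, angle_step_init = angle_step_init,
       tol = tol, max_iter = max_iter, weight_lambda = weight_lambda,
       min_step_deg = min_step_deg, start_offset = start_offset)
}

#' Iterative cutting-plane orientation optimization
#'
#' Deterministic coordinate descent over the two spherical angles of the
#' plane normal: at each iteration the four single-angle perturbations of
#' the current normal are sectioned and scored, the best is accepted if it
#' improves the objective, and the angular step is halved when none does.
#' Stops when the accepted objective change falls below `tol`, the step
#' falls below `min_step_deg`, or `max_iter` is reached. The plane is kept
#' passing through its initial anchor point (the projection of the mesh
#' centroid onto the initial plane).
#'
#' @param mesh A [surface_mesh()].
#' @param init Initial [plane()] (normal oriented medially).
#' @param cfg An [optimize_config()].
#' @return List with `plane`, `objective` (the [plane_objective()] at the
#'   optimum) and `trace` (data frame of accepted objective values,
#'   non-increasing).
#' @export
optimize_cutting_plane <- function(mesh, init, cfg = optimize_config()) {
  anchor_d <- plane_distance(init, colMeans(mesh$vertices))
  anchor <- colMeans(mesh$vertices) - anchor_d * init$normal

  evaluate <- function(nrm) {
    pl <- plane(nrm, point = anchor)
    span <- diff(range(mesh$vertices %*% pl$normal))
    sm <- section_series(mesh, pl, cfg$n_sections_per_condyle,
                         cfg$section_spacing, "medial", cfg$start_offset)
    sl <- section_series(mesh, pl, cfg$n_sections_per_condyle,
                         cfg$section_spacing, "lateral", cfg$start_offset)
    tryCatch(plane_objective(sm, sl, lambda = cfg$weight_lambda, span = span),
             error = function(e) NULL)
  }

  nrm <- init$normal
  cur <- evaluate(nrm)
  if (is.null(cur)) stop("objective not computable at the initial plane")
  step <- deg2rad(cfg$angle_step_init)
  trace <- data.frame(iter = 0, objective = cur$objective,
                      mean_eccentricity = cur$mean_eccentricity,
                      focal_dispersion = cur$focal_dispersion,
                      step_deg = rad2deg(step))
  iter <- 0
  while (iter < cfg$max_iter && step >= deg2rad(cfg$min_step_deg)) {
    fr <- plane_frame(plane(nrm, 0))
    cands <- list(rotate_about(nrm, fr$e1, step),
                  rotate_about(nrm, fr$e1, -step),
                  rotate_about(nrm, fr$e2, step),
                  rotate_about(nrm, fr$e2, -step))
    objs <- lapply(cands, evaluate)
    vals <- vapply(objs, function(o) if (is.null(o)) Inf else o$objective,
                   numeric(1))
    best <- which.min(vals)
    if (vals[best] < cur$objective) {
      improve <- cur$objective - vals[best]
      nrm <- unitize(cands[[best]])
      cur <- objs[[best]]
      iter <- iter + 1
      trace <- rbind(trace, data.frame(iter = iter, objective = cur$objective,
                                       mean_eccentricity = cur$mean_eccentricity,
                                       focal_dispersion = cur$focal_dispersion,
                                       step_deg = rad2deg(step)))
      if (improve < cfg$tol) break
    } else {
      step <- step / 2
    }
  }
  list(plane = plane(nrm, point = anchor), objective = cur, trace = trace)
}

#' Virtual medial resection
#'
#' Cuts the mesh with the plane and keeps the closed piece on the marker's
#' side, adding planar cap faces along the cut. Used to remove the medial
#' condylar region while preserving the lateral portion.
#'
#' @param mesh Watertight [surface_mesh()].
#' @param pl Cutting [plane()].
#' @param lateral_marker 3-point strictly on the side to keep.
#' @return A [surface_mesh()] (the input mesh, unchanged, when it lies
#'   entirely on the marker side).
#' @export
resect_medial <- function(mesh, pl, lateral_marker) {
  md <- plane_distance(pl, lateral_marker)
  if (abs(md) < 1e-9) stop("lateral marker lies on the cutting plane")
  sgn <- sign(md)
  d <- plane_distance(pl, mesh$vertices) * sgn
  if (all(d >= 0)) return(mesh)
  # nudge exactly-on-plane vertices to the kept side so every crossing edge
  # has a strict sign change (keeps the cut ring topologically consistent)
  d[abs(d) < 1e-9] <- 1e-9
  if (all(d <= 0)) stop("mesh lies entirely on the removed side")

  V <- mesh$vertices
  F <- mesh$faces
  keep_v <- d >= 0
  new_pts <- list()
  new_key <- character(0)
  get_cut <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    j <- match(key, new_key)
    if (!is.na(j)) return(j)
    t <- d[a] / (d[a] - d[b])
    p <- V[a, ] + t * (V[b, ] - V[a, ])
    new_key[length(new_key) + 1] <<- key
    new_pts[[length(new_pts) + 1]] <<- p
    length(new_pts)
  }
  out_faces <- list()
  cut_segs <- list()  # boundary segments (pairs of cut-point ids)
  nin <- rowSums(cbind(keep_v[F[, 1]], keep_v[F[, 2]], keep_v[F[, 3]]))
  for (fi in seq_len(nrow(F))) {
    tri <- F[fi, ]
    k <- keep_v[tri]
    if (nin[fi] == 3) { out_faces[[length(out_faces) + 1]] <- tri; next }
    if (nin[fi] == 0) next
    ins <- tri[k]; outs <- tri[!k]
    if (length(ins) == 1) {
      # keep small triangle
      c1 <- get_cut(ins, outs[1])
      c2 <- get_cut(ins, outs[2])
      # preserve winding: order outs as they appear after ins in the face cycle
      cyc <- c(tri, tri)
      pos <- which(cyc == ins)[1]
      nxt <- cyc[pos + 1]
      if (nxt == outs[1]) {
        out_faces[[length(out_faces) + 1]] <- c(ins, -c1, -c2)
        cut_segs[[length(cut_segs) + 1]] <- c(c1, c2)
      } else {
        out_faces[[length(out_faces) + 1]] <- c(ins, -c2, -c1)
        cut_segs[[length(cut_segs) + 1]] <- c(c2, c1)
      }
    } else {
      # keep quad
      c1 <- get_cut(ins[1], outs)
      c2 <- get_cut(ins[2], outs)
      cyc <- c(tri, tri)
      pos <- which(cyc == outs)[1]
      nxt <- cyc[pos + 1]
      if (nxt == ins[1]) {
        out_faces[[length(out_faces) + 1]] <- c(-c2, -c1, ins[1])
        out_faces[[length(out_faces) + 1]] <- c(-c2, ins[1], ins[2])
        cut_segs[[length(cut_segs) + 1]] <- c(c2, c1)
      } else {
        out_faces[[length(out_faces) + 1]] <- c(-c1, -c2, ins[2])
        out_faces[[length(out_faces) + 1]] <- c(-c1, ins[2], ins[1])
        cut_segs[[length(cut_segs) + 1]] <- c(c1, c2)
      }
    }
  }
  cutV <- do.call(rbind, new_pts)
  nV0 <- nrow(V)
  # negative indices refer to cut points
  faces <- do.call(rbind, lapply(out_faces, function(f)
    ifelse(f < 0, nV0 - f, f)))
  allV <- rbind(V, cutV)

  # cap: link cut segments into loops and fan-triangulate
  if (length(cut_segs) > 0) {
    segs <- do.call(rbind, cut_segs) + nV0
    nxt <- setNames(segs[, 2], segs[, 1])
    used <- rep(FALSE, nrow(segs))
    starts <- segs[, 1]
    seg_of <- setNames(seq_len(nrow(segs)), segs[, 1])
    for (si in seq_len(nrow(segs))) {
      if (used[si]) next
      loop <- segs[si, 1]
      used[si] <- TRUE
      curp <- segs[si, 2]
      while (!is.na(curp) && curp != loop[1]) {
        loop <- c(loop, curp)
        j <- seg_of[as.character(curp)]
        if (is.na(j) || used[j]) break
        used[j] <- TRUE
        curp <- segs[j, 2]
      }
      if (length(loop) >= 3) {
        ctr <- colMeans(allV[loop, , drop = FALSE])
        allV <- rbind(allV, ctr)
        ci <- nrow(allV)
        # cap normal must face away from the kept side (-sgn * plane normal)
        for (q in seq_along(loop)) {
          a <- loop[q]
          b <- loop[circ_idx(q + 1L, length(loop))]
          tri <- c(ci, a, b)
          nrm <- cross3(allV[a, ] - ctr, allV[b, ] - ctr)
          if (sum(nrm * pl$normal) * sgn > 0) tri <- c(ci, b, a)
          faces <- rbind(faces, tri)
        }
      }
    }
  }
  used_v <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(allV))
  remap[used_v] <- seq_along(used_v)
  surface_mesh(allV[used_v, , drop = FALSE], matrix(remap[faces], ncol = 3))
}
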