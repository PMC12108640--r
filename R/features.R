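# Curvature-based feature curves on the lateral condyle surface: per-vertex
# principal curvatures, high-curvature point selection, three-criterion
# region growing, and anatomical clipping to the CLR / anterior margin.

#' Per-vertex principal curvatures
#'
#' For each vertex a quadric height field is fitted over the neighbourhood
#' in the vertex tangent frame and the shape operator's eigen-decomposition
#' gives the principal curvatures (kappa1 >= kappa2, convex positive), the
#' Gaussian curvature K = kappa1 * kappa2, and the principal direction of
#' kappa1. The neighbourhood is the one-ring grown ring-by-ring until it
#' covers `radius` (iso-surfaced meshes carry sub-voxel jitter that a bare
#' one-ring fit amplifies; on clean parametric meshes `radius = 0`
#' reproduces the one-ring estimator).
#'
#' @param mesh Manifold [surface_mesh()] with outward-oriented faces.
#' @param radius Neighbourhood radius in mm; `NULL` for 2.5 x mean edge
#'   length, `0` for plain one-ring.
#' @param min_neighbors Minimum neighbour count (ring growth floor).
#' @return List of class `vertex_curvature`: `kappa1`, `kappa2`, `gaussian`,
#'   `principal_dir` (N x 3), `n_neighbors`; isolated/degenerate vertices
#'   carry `NA`.
#' @export
vertex_curvatures <- function(mesh, radius = NULL, min_neighbors = 6) {
  if (is.null(radius)) radius <- 2.5 * mean_edge_length(mesh)
  res <- cn_vertex_curvature(mesh$vertices, mesh$faces, min_neighbors, radius)
  structure(list(kappa1 = res[, 1], kappa2 = res[, 2], gaussian = res[, 3],
                 principal_dir = res[, 4:6, drop = FALSE],
                 n_neighbors = res[, 7]),
            class = "vertex_curvature")
}

#' High-curvature feature points
#'
#' Selects the vertex set with curvature above a threshold. The threshold
#' is either absolute (`tau`) or the given percentile of the finite
#' curvature values.
#'
#' @param curv A [vertex_curvatures()] result.
#' @param tau Absolute threshold; `NULL` to use `percentile`.
#' @param percentile Percentile (0-100) used when `tau` is `NULL`.
#' @param measure `"gaussian"` (K, the default) or `"max_principal"`
#'   (kappa1, the more robust channel on iso-surfaced meshes).
#' @return Integer vertex ids; the resolved threshold is attached as
#'   attribute `tau`.
#' @export
feature_points <- function(curv, tau = NULL, percentile = 90,
                           measure = c("gaussian", "max_principal")) {
  measure <- match.arg(measure)
  val <- if (measure == "gaussian") curv$gaussian else curv$kappa1
  if (is.null(tau))
    tau <- as.numeric(quantile(val, percentile / 100, na.rm = TRUE))
  ids <- which(!is.na(val) & val > tau)
  attr(ids, "tau") <- tau
  attr(ids, "measure") <- measure
  ids
}

#' Thin a feature-point band by across-ridge non-maximum suppression
#'
#' High-curvature vertex sets selected on an iso-surfaced mesh form bands
#' several vertices wide. Analogous to the non-maximum suppression step of
#' edge detection, a feature point is kept only if its curvature measure is
#' maximal among nearby feature points lying roughly along its own
#' principal direction (which runs across the ridge), reducing the band to
#' a curve-like chain before region growing.
#'
#' @param mesh A [surface_mesh()].
#' @param curv A [vertex_curvatures()] result.
#' @param pf Feature ids from [feature_points()].
#' @param radius Suppression radius (mm); `NULL` for 2 x mean edge length.
#' @param align Minimum |cosine| between the displacement and the principal
#'   direction for a neighbour to compete.
#' @return Thinned feature ids (same attributes as `pf`).
#' @export
thin_feature_points <- function(mesh, curv, pf, radius = NULL, align = 0.6) {
  if (is.null(radius)) radius <- 2 * mean_edge_length(mesh)
  measure <- attr(pf, "measure")
  val <- if (identical(measure, "max_principal")) curv$kappa1 else curv$gaussian
  P <- mesh$vertices[pf, , drop = FALSE]
  v <- val[pf]
  Dir <- curv$principal_dir[pf, , drop = FALSE]
  nn <- cn_knn(P, P, min(30L, nrow(P)))
  keep <- rep(TRUE, length(pf))
  for (i in seq_along(pf)) {
    js <- nn$idx[i, nn$dist[i, ] <= radius]
    js <- js[js != i]
    if (length(js) == 0) next
    disp <- sweep(P[js, , drop = FALSE], 2, P[i, ])
    dn <- sqrt(rowSums(disp^2))
    co <- abs(as.numeric(disp %*% Dir[i, ])) / pmax(dn, 1e-12)
    comp <- js[co >= align]
    if (length(comp) > 0 && any(v[comp] > v[i])) keep[i] <- FALSE
  }
  out <- pf[keep]
  attr(out, "tau") <- attr(pf, "tau")
  attr(out, "measure") <- measure
  out
}

#' Region-growing configuration
#'
#' @param eps Spatial proximity bound (mm); `NULL` for 2.5 x mean edge
#'   length of the mesh at growth time.
#' @param sigma_k Curvature-consistency bound (same units as the growth
#'   measure); `NULL` for the interquartile range of the measure over the
#'   feature points.
#' @param theta_max Direction-continuity bound (degrees, <= 90).
#' @export
grow_config <- function(eps = NULL, sigma_k = NULL, theta_max = 30) {
  if (theta_max <= 0 || theta_max > 90) stop("theta_max must be in (0, 90]")
  if (!is.null(eps) && eps <= 0) stop("eps must be positive")
  if (!is.null(sigma_k) && sigma_k <= 0) stop("sigma_k must be positive")
  list(eps = eps, sigma_k = sigma_k, theta_max = theta_max)
}

#' Grow feature points into ordered curves
#'
#' Greedy region growing: starting from the highest-curvature seed, the
#' curve is extended at its endpoints by the nearest remaining feature
#' point that satisfies all three criteria - spatial proximity
#' (distance <= eps), curvature consistency (|K_i - K_j| <= sigma_k) and
#' directional continuity (the angle between the tangent vectors at
#' adjacent points, realized as the angle between consecutive growth
#' steps, <= theta_max; this keeps the chain marching along the ridge
#' instead of weaving across a several-vertex-wide feature band). When
#' neither endpoint can grow, the next seed is taken from the remaining
#' points. Curves with fewer than 3 points are discarded. Deterministic for
#' a fixed vertex ordering.
#'
#' @param mesh A [surface_mesh()].
#' @param curv A [vertex_curvatures()] result.
#' @param pf Feature vertex ids from [feature_points()].
#' @param cfg A [grow_config()].
#' @return List of `feature_curve` objects (fields `vertex_ids`, `points`,
#'   `label`).
#' @export
grow_curves <- function(mesh, curv, pf, cfg = grow_config()) {
  if (length(pf) == 0) stop("empty feature point set")
  measure <- attr(pf, "measure")
  val <- if (identical(measure, "max_principal")) curv$kappa1 else curv$gaussian
  eps <- if (is.null(cfg$eps)) 2.5 * mean_edge_length(mesh) else cfg$eps
  K <- val[pf]
  sigma_k <- if (is.null(cfg$sigma_k)) {
    s <- IQR(K, na.rm = TRUE)
    if (!is.finite(s) || s <= 0) s <- Inf
    s
  } else cfg$sigma_k
  cos_th <- cos(deg2rad(cfg$theta_max))
  P <- mesh$vertices[pf, , drop = FALSE]
  n <- length(pf)
  remaining <- rep(TRUE, n)
  curves <- list()

  next_point <- function(e, prev_dir) {
    # nearest remaining candidate satisfying all three criteria
    d2 <- (P[, 1] - P[e, 1])^2 + (P[, 2] - P[e, 2])^2 + (P[, 3] - P[e, 3])^2
    ok <- remaining & d2 <= eps^2 & abs(K - K[e]) <= sigma_k
    ok[e] <- FALSE
    if (!any(ok)) return(NA_integer_)
    cand <- which(ok)
    if (!is.null(prev_dir)) {
      step <- sweep(P[cand, , drop = FALSE], 2, P[e, ])
      co <- as.numeric(step %*% prev_dir) / pmax(sqrt(rowSums(step^2)), 1e-12)
      cand <- cand[co >= cos_th]
      if (length(cand) == 0) return(NA_integer_)
    }
    cand[which.min(d2[cand])]
  }

  while (any(remaining)) {
    seed <- which(remaining)[which.max(K[remaining])]
    remaining[seed] <- FALSE
    chain <- seed
    # grow at the tail, then flip and grow at the (new) tail
    for (pass in 1:2) {
      repeat {
        e <- chain[length(chain)]
        prev_dir <- if (length(chain) >= 2) {
          d <- P[e, ] - P[chain[length(chain) - 1], ]
          d / max(vnorm(d), 1e-12)
        } else NULL
        nx <- next_point(e, prev_dir)
        if (is.na(nx)) break
        remaining[nx] <- FALSE
        chain <- c(chain, nx)
      }
      chain <- rev(chain)
    }
    if (length(chain) >= 3) {
      curves[[length(curves) + 1]] <- structure(
        list(vertex_ids = pf[chain],
             points = mesh$vertices[pf[chain], , drop = FALSE],
             label = "unlabeled"),
        class = "feature_curve")
    }
  }
  curves
}

#' @export
print.feature_curve <- function(x, ...) {
  cat(sprintf("feature_curve [%s]: %d points, length %.2f mm\n", x$label,
              nrow(x$points), curve_length(x)))
  invisible(x)
}

curve_length <- function(curve) {
  sum(sqrt(rowSums(diff(curve$points)^2)))
}

#' Anatomical box region
#'
#' Oriented box Omega = {p : l_i <= <p - c, e_i> <= u_i} used to clip
#' feature curves to the lateral condylar region.
#'
#' @param center 3-point c (mm).
#' @param axes 3x3 matrix with orthonormal columns e1, e2, e3.
#' @param lower,upper Bounds l_i < u_i (mm) per axis.
#' @return Object of class `anatomical_region`.
#' @export
anatomical_region <- function(center, axes, lower, upper) {
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop("axes must be orthonormal")
  if (any(lower >= upper)) stop("each lower bound must be below the upper")
  structure(list(center = as.numeric(center), axes = axes,
                 lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "anatomical_region")
}

region_contains <- function(region, pts) {
  local <- sweep(rbind3(pts), 2, region$center) %*% region$axes
  ok <- rep(TRUE, nrow(local))
  for (i in 1:3)
    ok <- ok & local[, i] >= region$lower[i] & local[, i] <= region$upper[i]
  ok
}

#' Default lateral-condylar region from the optimized sagittal frame
#'
#' Axes: the (medially-oriented) sagittal plane normal and the two in-plane
#' frame directions. Bounds: the lateral mesh's bounding box in those axes,
#' shrunk by the given fraction at the anterior and posterior ends.
#'
#' @param lateral_mesh The resected lateral [surface_mesh()].
#' @param pl The optimized sagittal [plane()].
#' @param ap_shrink Fraction removed from each anteroposterior end.
#' @param ap_axis Which region axis (1-3) is anteroposterior.
#' @param superior_limit Optional world-space point (e.g. a notch-roof
#'   landmark): the region is capped at its height along the superior
#'   axis, excluding the shaft and intercondylar roof structures that lie
#'   above the condyle proper.
#' @param superior_axis Which region axis (1-3) is superior.
#' @param cut_margin Margin (mm) excluded next to the resection plane, so
#'   the artificial cut face and its sharp rim do not enter the region.
#' @return An [anatomical_region()].
#' @export
lateral_condyle_region <- function(lateral_mesh, pl, ap_shrink = 0.1,
                                   ap_axis = 3, superior_limit = NULL,
                                   superior_axis = 2, cut_margin = 2) {
  fr <- plane_frame(pl)
  axes <- cbind(pl$normal, fr$e1, fr$e2)
  ctr <- colMeans(lateral_mesh$vertices)
  local <- sweep(lateral_mesh$vertices, 2, ctr) %*% axes
  lo <- apply(local, 2, min)
  hi <- apply(local, 2, max)
  shrink <- (hi[ap_axis] - lo[ap_axis]) * ap_shrink
  lo[ap_axis] <- lo[ap_axis] + shrink
  hi[ap_axis] <- hi[ap_axis] - shrink
  if (!is.null(superior_limit)) {
    lim <- sum((as.numeric(superior_limit) - ctr) * axes[, superior_axis])
    hi[superior_axis] <- min(hi[superior_axis], lim)
  }
  if (cut_margin > 0) {
    # the resected mesh lies on the far side of the plane along axis 1;
    # its cut face sits at the high end of the local axis-1 range
    hi[1] <- hi[1] - cut_margin
  }
  anatomical_region(ctr, axes, lo - 1e-6, hi + 1e-6)
}

#' Clip feature curves to an anatomical region and label them
#'
#' Points outside the region are removed and curves are split at the
#' exits. Among the substantial retained segments (arc length at least
#' `label_min_frac` of the longest), the one with the most posterior
#' centroid is labelled `CLR` and the most anterior one
#' `anterior_margin` (a single candidate is labelled `CLR`); the rest stay
#' `unlabeled`.
#'
#' @param curves List of `feature_curve`s from [grow_curves()].
#' @param region An [anatomical_region()].
#' @param anterior_dir World-space anterior direction (for labelling).
#' @param min_points Minimum points per retained segment.
#' @param label_min_frac Length fraction of the longest segment required to
#'   compete for a label.
#' @return List of labelled `feature_curve`s (empty, with a warning, when
#'   nothing intersects the region).
#' @export
clip_to_region <- function(curves, region, anterior_dir = c(0, 1, 0),
                           min_points = 3, label_min_frac = 0.5) {
  segs <- list()
  for (cv in curves) {
    inside <- region_contains(region, cv$points)
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      if (length(idx) < min_points) next
      segs[[length(segs) + 1]] <- structure(
        list(vertex_ids = cv$vertex_ids[idx],
             points = cv$points[idx, , drop = FALSE],
             label = "unlabeled"),
        class = "feature_curve")
    }
  }
  if (length(segs) == 0) {
    warning("no feature curve intersects the anatomical region")
    return(list())
  }
  lens <- vapply(segs, curve_length, numeric(1))
  cand <- which(lens >= label_min_frac * max(lens))
  ap <- vapply(segs[cand], function(s)
    sum(colMeans(s$points) * unitize(anterior_dir)), numeric(1))
  segs[[cand[which.min(ap)]]]$label <- "CLR"
  if (length(cand) > 1) segs[[cand[which.max(ap)]]]$label <- "anterior_margin"
  segs
}

#' Extract labelled feature curves from a lateral condyle mesh
#'
#' Convenience pipeline: per-vertex curvature, feature-point selection,
#' region growing and anatomical clipping, returning the labelled curves
#' (CLR and anterior margin). The operating point (95th-percentile
#' maximum-principal-curvature threshold) is chosen for iso-surfaced CT
#' meshes, where the Gaussian channel at the 90th percentile admits too
#' much discretization noise for reliable curve growth.
#'
#' @param lateral_mesh The resected lateral [surface_mesh()].
#' @param pl The optimized sagittal [plane()] (medially-oriented normal).
#' @param superior_limit Optional world point capping the condylar region
#'   superiorly (e.g. a notch-roof landmark).
#' @param percentile Feature-point percentile threshold.
#' @param measure Curvature channel for [feature_points()].
#' @param curvature_radius Neighbourhood radius for [vertex_curvatures()].
#' @param cfg A [grow_config()].
#' @param anterior_dir World anterior direction for labelling.
#' @return List of labelled `feature_curve`s.
#' @export
extract_clr <- function(lateral_mesh, pl, superior_limit = NULL,
                        percentile = 95, measure = "max_principal",
                        curvature_radius = NULL, cfg = grow_config(),
                        anterior_dir = c(0, 1, 0)) {
  cv <- vertex_curvatures(lateral_mesh, radius = curvature_radius)
  reg <- lateral_condyle_region(lateral_mesh, pl,
                                superior_limit = superior_limit)
  # resolve the percentile threshold within the condylar region, so sharp
  # structures outside it (shaft rim, roof edges) do not inflate the cutoff
  in_reg <- region_contains(reg, lateral_mesh$vertices)
  val <- if (measure == "max_principal") cv$kappa1 else cv$gaussian
  tau <- as.numeric(quantile(val[in_reg], percentile / 100, na.rm = TRUE))
  pf <- which(in_reg & !is.na(val) & val > tau)
  attr(pf, "tau") <- tau
  attr(pf, "measure") <- measure
  curves <- grow_curves(lateral_mesh, cv, pf, cfg)
  clip_to_region(curves, reg, anterior_dir = anterior_dir)
}

#' Write feature curves as JSON polylines
#'
#' @param curves List of `feature_curve`s.
#' @param path Output JSON path.
#' @export
write_curves_json <- function(curves, path) {
  payload <- lapply(curves, function(cv)
    list(label = cv$label, points_mm = unname(as.matrix(cv$points))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
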