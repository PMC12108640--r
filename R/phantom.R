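# Synthetic distal-femur phantom with analytic ground truth.
#
# The phantom is a constructive solid: two ellipsoidal condylar lobes on the
# epicondylar (x) axis, a planar-roofed "bridge" joining them above the
# intercondylar notch (the roof centerline plays the role of Blumensaat's
# line), a shaft stub, and a capsular-line crease planted as a raised
# triangular wedge running along an arc on the lateral lobe surface; the
# wedge apex is a sharp (C0, discontinuous-normal) ridge line with exact
# ground truth. Every downstream stage can be tested against the truth.

#' Phantom specification
#'
#' Anatomical axes: +x mediolateral (lateral side positive, the epicondylar
#' axis), +y anteroposterior (anterior positive), +z inferosuperior
#' (superior positive). Units mm.
#'
#' Per-lobe radii are (rx, ry, rz); the defaults use ry = rz so that
#' sections perpendicular to the epicondylar axis are exactly circular,
#' which is the geometric idealization behind the sagittal-plane
#' optimization objective.
#'
#' @param condyle_radii_medial,condyle_radii_lateral Semi-axes (mm).
#' @param condyle_separation Center-to-center distance of the lobes (mm).
#' @param notch_depth Vertical drop from lobe-center height to the notch
#'   roof plane at y = 0 (mm); larger values put the roof lower.
#' @param roof_tilt_deg Tilt of the notch roof plane about the x axis
#'   (degrees); the roof rises anteriorly, as Blumensaat's line does in a
#'   lateral view.
#' @param crease_start_deg,crease_span_deg Arc of the planted crease on the
#'   lateral lobe, measured in the sagittal plane from the inferior
#'   direction towards posterior; span must lie in (0, 180].
#' @param crease_height Apex height (mm) of the planted ridge wedge above
#'   the lobe surface; the apex is the high-curvature ridge line.
#' @param crease_halfwidth Half-width (mm) of the ridge wedge footprint in
#'   the mediolateral direction.
#' @param crease_plane_frac Position of the crease plane along the lateral
#'   lobe x semi-axis, as a fraction towards the notch (0 = lobe center).
#' @param voxel_spacing Voxel pitch mm (scalar or per-axis).
#' @param noise_sd Gaussian intensity noise SD (CT-number-like units).
#' @param bone_intensity Foreground intensity (background is 0).
#' @param seed Integer seed; identical (spec, seed) pairs give bit-identical
#'   volumes.
#' @param include_bridge,include_shaft,include_crease Toggles for the
#'   non-lobe components (useful for reduced geometric fixtures).
#' @param margin_mm Padding between geometry and the volume boundary.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(condyle_radii_medial = c(13, 26, 26),
                         condyle_radii_lateral = c(13, 28, 28),
                         condyle_separation = 30,
                         notch_depth = 24,
                         roof_tilt_deg = 25,
                         crease_start_deg = -10,
                         crease_span_deg = 100,
                         crease_height = 2,
                         crease_halfwidth = 1.75,
                         crease_plane_frac = 0.5,
                         voxel_spacing = 0.5,
                         noise_sd = 15,
                         bone_intensity = 700,
                         seed = 1,
                         include_bridge = TRUE,
                         include_shaft = TRUE,
                         include_crease = TRUE,
                         margin_mm = 3) {
  spec <- list(condyle_radii_medial = as.numeric(condyle_radii_medial),
               condyle_radii_lateral = as.numeric(condyle_radii_lateral),
               condyle_separation = condyle_separation,
               notch_depth = notch_depth,
               roof_tilt_deg = roof_tilt_deg,
               crease_start_deg = crease_start_deg,
               crease_span_deg = crease_span_deg,
               crease_height = crease_height,
               crease_halfwidth = crease_halfwidth,
               crease_plane_frac = crease_plane_frac,
               voxel_spacing = rep(as.numeric(voxel_spacing), length.out = 3),
               noise_sd = noise_sd,
               bone_intensity = bone_intensity,
               seed = as.integer(seed),
               include_bridge = include_bridge,
               include_shaft = include_shaft,
               include_crease = include_crease,
               margin_mm = margin_mm)
  if (any(spec$condyle_radii_medial <= 0) || any(spec$condyle_radii_lateral <= 0))
    stop("condyle radii must be positive")
  if (any(spec$voxel_spacing <= 0)) stop("voxel spacing must be positive")
  if (spec$crease_span_deg <= 0 || spec$crease_span_deg > 180)
    stop("crease span must be in (0, 180] degrees")
  if (spec$crease_height <= 0 || spec$crease_halfwidth <= 0)
    stop("crease wedge dimensions must be positive")
  structure(spec, class = "phantom_spec")
}

# Derived geometry shared by voxelization and ground truth.
phantom_geometry <- function(spec) {
  d <- spec$condyle_separation / 2
  rm_ <- spec$condyle_radii_medial
  rl <- spec$condyle_radii_lateral
  roof_m <- tan(deg2rad(spec$roof_tilt_deg))
  roof_z0 <- max(rm_[3], rl[3]) - spec$notch_depth
  bridge <- list(halfwidth = d * 0.55, ylim = c(-16, 16) / 28 * rl[2],
                 thickness = 0.5 * rl[3])
  shaft <- list(radius = 0.5 * (rm_[1] + rl[1] + spec$condyle_separation) / 2,
                ycenter = -0.05 * rl[2],
                zlim = c(0.55, 1.25) * max(rm_[3], rl[3]))
  xc <- d - spec$crease_plane_frac * rl[1]
  f <- sqrt(max(0, 1 - ((xc - d) / rl[1])^2))
  crease <- list(plane_x = xc,
                 center = c(xc, 0, 0),
                 radius = 0.5 * (rl[2] + rl[3]) * f,
                 a0 = deg2rad(spec$crease_start_deg),
                 a1 = deg2rad(spec$crease_start_deg + spec$crease_span_deg),
                 rho = spec$crease_height,
                 halfwidth = spec$crease_halfwidth,
                 ell = c(rl[2] * f, rl[3] * f))
  list(d = d, rmed = rm_, rlat = rl, cmed = c(-d, 0, 0), clat = c(d, 0, 0),
       roof_m = roof_m, roof_z0 = roof_z0, bridge = bridge, shaft = shaft,
       crease = crease)
}

# Points on the planted crease arc, projected radially onto the lateral-lobe
# section ellipse (exact when ry == rz); `offset` pushes them radially
# outwards (the bead crest sits at offset = tube radius).
crease_arc_points <- function(geom, n = 200, offset = 0) {
  cr <- geom$crease
  a <- seq(cr$a0, cr$a1, length.out = n)
  dir_y <- -sin(a)
  dir_z <- -cos(a)
  # radial scale onto the section ellipse (y/ay)^2 + (z/az)^2 = 1
  s <- 1 / sqrt((dir_y / cr$ell[1])^2 + (dir_z / cr$ell[2])^2) + offset
  cbind(cr$plane_x, s * dir_y, s * dir_z)
}

roof_z <- function(geom, y) geom$roof_z0 + geom$roof_m * y

# Analytic lateral-view (projection along +x) silhouette support of the
# lateral half, as extreme dot products with a 2D direction in (y, z).
lateral_silhouette_support <- function(spec, geom, u) {
  cand <- rbind(c(0, 0))  # lobe center
  # ellipse support points handled analytically below; collect corners:
  if (spec$include_bridge) {
    yl <- geom$bridge$ylim
    cand <- rbind(cand,
                  cbind(yl, roof_z(geom, yl)),
                  cbind(yl, roof_z(geom, yl) + geom$bridge$thickness))
  }
  if (spec$include_shaft) {
    sy <- geom$shaft$ycenter + c(-1, 1) * geom$shaft$radius
    cand <- rbind(cand, as.matrix(expand.grid(sy, geom$shaft$zlim)))
  }
  dots <- as.numeric(cand %*% u)
  es <- sqrt((geom$rlat[2] * u[1])^2 + (geom$rlat[3] * u[2])^2)
  c(min(c(dots, -es)), max(c(dots, es)))
}

# Ground-truth Bernard-Hertel construction in the (y, z) projection plane.
phantom_bh_truth <- function(spec, geom) {
  phi <- deg2rad(spec$roof_tilt_deg)
  u <- c(cos(phi), sin(phi))          # roof direction, anterior-positive
  w <- c(sin(phi), -cos(phi))         # perpendicular, inferior-positive
  b0 <- c(0, geom$roof_z0)            # roof line point at y = 0
  tr <- lateral_silhouette_support(spec, geom, u)
  h_max <- lateral_silhouette_support(spec, geom, w)[2] - sum(w * b0)
  L_D <- diff(tr)
  O <- b0 + (tr[1] - sum(u * b0)) * u
  fp2 <- O + 0.248 * L_D * u + 0.285 * h_max * w
  list(u = u, w = w, roof_point = b0, t_range = tr, L_D = L_D, L_H = h_max,
       origin2d = O, footprint2d = fp2)
}

#' Generate a synthetic distal-femur phantom volume with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [volume_image()]) and `truth`, a list with
#'   fields `epicondylar_axis`, `notch_anterior_pt`, `notch_posterior_pt`,
#'   `crease_polyline`, `blumensaat_polyline`, `footprint_pt`,
#'   `lateral_marker_pt`, `medial_marker_pt`, `threshold`, and `bh` (the
#'   analytic lateral-view grid construction).
#' @export
make_femur_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  sp <- spec$voxel_spacing
  m <- spec$margin_mm

  lo <- c(-geom$d - geom$rmed[1], -max(geom$rmed[2], geom$rlat[2]),
          -max(geom$rmed[3], geom$rlat[3])) - m
  hi <- c(geom$d + geom$rlat[1], max(geom$rmed[2], geom$rlat[2]),
          max(geom$rmed[3], geom$rlat[3])) + m
  if (spec$include_shaft) hi[3] <- max(hi[3], geom$shaft$zlim[2] + m)
  ax <- seq(lo[1], hi[1], by = sp[1])
  ay <- seq(lo[2], hi[2], by = sp[2])
  az <- seq(lo[3], hi[3], by = sp[3])
  nd <- c(length(ax), length(ay), length(az))
  if (any(nd < 8)) stop("phantom lobes do not fit the volume bounds")

  X <- array(rep(ax, times = nd[2] * nd[3]), nd)
  Y <- array(rep(rep(ay, each = nd[1]), times = nd[3]), nd)
  Z <- array(rep(az, each = nd[1] * nd[2]), nd)

  inside <-
    ((X - geom$cmed[1]) / geom$rmed[1])^2 + (Y / geom$rmed[2])^2 +
      (Z / geom$rmed[3])^2 <= 1
  inside <- inside |
    (((X - geom$clat[1]) / geom$rlat[1])^2 + (Y / geom$rlat[2])^2 +
       (Z / geom$rlat[3])^2 <= 1)
  if (spec$include_bridge) {
    zr <- roof_z(geom, Y)
    inside <- inside |
      (abs(X) <= geom$bridge$halfwidth &
         Y >= geom$bridge$ylim[1] & Y <= geom$bridge$ylim[2] &
         Z >= zr & Z <= zr + geom$bridge$thickness)
  }
  if (spec$include_shaft) {
    inside <- inside |
      (Z >= geom$shaft$zlim[1] & Z <= geom$shaft$zlim[2] &
         X^2 + (Y - geom$shaft$ycenter)^2 <= geom$shaft$radius^2)
  }
  if (spec$include_crease) {
    cr <- geom$crease
    ryz <- sqrt(Y^2 + Z^2)
    alpha <- atan2(-Y, -Z)
    in_span <- alpha >= cr$a0 & alpha <= cr$a1
    dx <- abs(X - cr$plane_x)
    # local radial position of the lobe surface along each voxel's direction
    fx2 <- pmax(0, 1 - ((X - geom$clat[1]) / geom$rlat[1])^2)
    uy <- ifelse(ryz > 1e-9, Y / ryz, 0)
    uz <- ifelse(ryz > 1e-9, Z / ryz, -1)
    denom <- sqrt((uy / geom$rlat[2])^2 + (uz / geom$rlat[3])^2)
    s_loc <- ifelse(fx2 > 0 & denom > 0, sqrt(fx2) / denom, -Inf)
    ridge <- in_span & dx <= cr$halfwidth & is.finite(s_loc) &
      ryz <= s_loc + cr$rho * (1 - dx / cr$halfwidth)
    inside <- inside | ridge
  }

  vox <- array(spec$bone_intensity * as.numeric(inside), nd)
  if (spec$noise_sd > 0) {
    vox <- vox + withr::with_seed(
      spec$seed, array(rnorm(prod(nd), 0, spec$noise_sd), nd))
  }
  vol <- volume_image(vox, spacing = sp, origin = lo)

  yb <- geom$bridge$ylim
  blum_y <- seq(yb[1], yb[2], length.out = 50)
  truth <- list(
    epicondylar_axis = unitize(geom$clat - geom$cmed),
    notch_anterior_pt = c(0, yb[2], roof_z(geom, yb[2])),
    notch_posterior_pt = c(0, yb[1], roof_z(geom, yb[1])),
    crease_polyline = crease_arc_points(geom, 200, offset = geom$crease$rho),
    blumensaat_polyline = cbind(0, blum_y, roof_z(geom, blum_y)),
    lateral_marker_pt = geom$clat,
    medial_marker_pt = geom$cmed,
    threshold = spec$bone_intensity / 2,
    geom = geom)
  bh <- phantom_bh_truth(spec, geom)
  truth$bh <- bh
  truth$footprint_pt <- c(geom$clat[1], bh$footprint2d)
  list(volume = vol, truth = truth)
}

#' Reconstruct the phantom surface mesh from its volume
#'
#' Convenience wrapper running threshold segmentation, morphological
#' refinement and iso-surface extraction with the phantom's known threshold.
#'
#' @param ph Result of [make_femur_phantom()].
#' @param morph_radius Closing radius in voxels.
#' @param smooth_sigma Indicator smoothing sigma (voxels).
#' @return A [surface_mesh()].
#' @export
phantom_mesh <- function(ph, morph_radius = 1, smooth_sigma = 1) {
  mask <- segment_volume(ph$volume, ph$truth$threshold)
  mask <- refine_mask(mask, morph_radius)
  extract_surface(mask, ph$volume$spacing, ph$volume$origin, smooth_sigma)
}
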