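# Pinhole camera model and synthetic arthroscopic-frame rendering.
# Conventions (fixed project-wide): image origin top-left, x right, y down,
# pixel coordinates 0-based; camera looks along +z in camera space;
# world-to-camera map is Xc = R Xw + t.

#' Pinhole camera model
#'
#' @param fx,fy Focal lengths in px.
#' @param cx,cy Principal point in px (0-based image coordinates).
#' @param width,height Image size in px.
#' @param R 3x3 world-to-camera rotation.
#' @param t Translation 3-vector (mm): `Xc = R Xw + t`.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(fx, fy, cx, cy, width, height, R = diag(3),
                         t = c(0, 0, 0)) {
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 R = R, t = as.numeric(t)), class = "camera_model")
}

#' Camera looking at a target point
#'
#' @param eye Camera center in world mm.
#' @param target Point the optical axis passes through.
#' @param up Approximate up direction in world space (maps to image -y).
#' @param fx,fy,cx,cy,width,height Intrinsics, as in [camera_model()].
#' @export
look_at_camera <- function(eye, target, up = c(0, 0, 1),
                           fx = 400, fy = 400, cx = NULL, cy = NULL,
                           width = 320, height = 240) {
  if (is.null(cx)) cx <- (width - 1) / 2
  if (is.null(cy)) cy <- (height - 1) / 2
  zc <- unitize(as.numeric(target) - as.numeric(eye))
  xc <- cross3(zc, unitize(up))   # image x: right
  if (vnorm(xc) < 1e-8) stop("up direction parallel to view direction")
  xc <- unitize(xc)
  yc <- cross3(zc, xc)            # image y: down
  R <- rbind(xc, yc, zc)
  dimnames(R) <- NULL
  camera_model(fx, fy, cx, cy, width, height, R, -as.numeric(R %*% eye))
}

#' Project world points through a camera
#'
#' @param camera A [camera_model()].
#' @param pts N x 3 world points (mm).
#' @return N x 3 matrix with columns u, v (px) and depth z (mm).
#' @export
project_points <- function(camera, pts) {
  pc <- sweep(rbind3(pts) %*% t(camera$R), 2, -camera$t)
  cbind(u = camera$fx * pc[, 1] / pc[, 3] + camera$cx,
        v = camera$fy * pc[, 2] / pc[, 3] + camera$cy,
        z = pc[, 3])
}

#' Render a synthetic arthroscopic-style frame
#'
#' Pinhole projection with z-buffering and headlight Lambertian shading (the
#' light rides on the scope, as in arthroscopy), plus optional Gaussian
#' speckle noise. The planted capsular crease is rendered brighter than the
#' surrounding bone (the "white line" appearance that makes the CLR a
#' usable landmark). Also returns the exact pinhole projection of the
#' crease polyline, culled to visible points via the depth buffer.
#'
#' @param mesh A [surface_mesh()].
#' @param camera A [camera_model()].
#' @param truth Phantom truth list (for `crease_polyline`), or `NULL`.
#' @param noise_sd Speckle noise SD in intensity units (unit scale).
#' @param seed Seed for the speckle noise.
#' @param base_albedo Albedo of ordinary bone surface.
#' @param crease_albedo Albedo of faces within `crease_width` of the
#'   planted crease.
#' @param crease_width Half-width (mm) of the bright crease band.
#' @return List with `image` (h x w matrix, values in 0..1), `depth`,
#'   `projected_crease` (visible crease points, columns u/v in px) and
#'   `projected_crease_all` (every projected point with its depth).
#' @export
render_arthro_frame <- function(mesh, camera, truth = NULL, noise_sd = 0,
                                seed = 1, base_albedo = 0.55,
                                crease_albedo = 1, crease_width = 0.8) {
  albedo <- rep(base_albedo, nrow(mesh$faces))
  if (!is.null(truth) && crease_albedo != base_albedo) {
    fc <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
             mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
    nn <- cn_knn(truth$crease_polyline, fc, 1)
    albedo[nn$dist[, 1] <= crease_width] <- crease_albedo
  }
  res <- cn_raster_mesh(mesh$vertices, mesh$faces,
                        camera$fx, camera$fy, camera$cx, camera$cy,
                        camera$R, camera$t, camera$width, camera$height,
                        albedo)
  if (!any(is.finite(res$depth))) stop("camera frustum does not see the mesh")
  img <- res$image
  if (noise_sd > 0) {
    img <- img + withr::with_seed(
      seed, matrix(rnorm(length(img), 0, noise_sd), nrow(img)))
    img <- pmin(pmax(img, 0), 1)
  }
  projected_crease <- NULL
  projected_all <- NULL
  if (!is.null(truth)) {
    pr <- project_points(camera, truth$crease_polyline)
    projected_all <- pr
    ui <- round(pr[, 1]) + 1
    vi <- round(pr[, 2]) + 1
    ok <- pr[, 3] > 0 & ui >= 1 & ui <= camera$width & vi >= 1 &
      vi <= camera$height
    vis <- ok
    vis[ok] <- pr[ok, 3] <= res$depth[cbind(vi[ok], ui[ok])] + 1.5
    projected_crease <- pr[vis, 1:2, drop = FALSE]
  }
  list(image = img, depth = res$depth, projected_crease = projected_crease,
       projected_crease_all = projected_all)
}
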