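# Frame-level registration: enhancement, edges, SIFT initial alignment
# between the frame edge map and a rendering of the projected model curves,
# then ICP between frame edge points and model curve points.

#' Register an arthroscopic-style frame to projected model curves
#'
#' Pipeline: adaptive histogram equalization of the frame, Canny edge
#' extraction, SIFT keypoint matching for the initial alignment, then 2D
#' rigid ICP between the model curve points and the frame edge points. The
#' two SIFT inputs are brought into a common representation first - soft
#' distance-transform images exp(-d / sigma) of the model curves and of
#' the frame edge map - because difference-of-Gaussian keypoints are
#' unstable on thin line renderings. The returned mapping takes model
#' pixel coordinates into frame pixel coordinates (the inverse view of the
#' arthroscopic-to-CT mapping).
#'
#' @param frame Grayscale frame matrix in 0..1.
#' @param model_curves List of N x 2 matrices: projected model curves in mm
#'   (e.g. the projected CLR and silhouette boundary).
#' @param calib Calibration in mm per px.
#' @param tau Ratio-test threshold for the SIFT stage.
#' @param icp_tol,icp_max_iter ICP convergence controls.
#' @param dt_sigma Length scale (px) of the soft distance transform fed to
#'   SIFT.
#' @return List of class `frame_registration`: `transform`
#'   (a [rigid_transform2d()], px), `rmse_mm`, `n_matches`, `status`
#'   (`"ok"` or `"failed"`), `edges`, and `diagnostics`.
#' @export
register_frame <- function(frame, model_curves, calib = 0.1, tau = 0.75,
                           icp_tol = 1e-6, icp_max_iter = 100,
                           dt_sigma = 8) {
  frame <- as_gray(frame)
  h <- nrow(frame); w <- ncol(frame)
  diagnostics <- list()
  fail <- function(reason, edges = NULL) {
    structure(list(transform = NULL, rmse_mm = NA_real_, n_matches = 0L,
                   status = "failed", edges = edges,
                   diagnostics = c(diagnostics, list(reason = reason))),
              class = "frame_registration")
  }
  enh <- enhance(frame)
  edges <- detect_edges(enh)
  ep <- edge_points(edges)
  if (nrow(ep) < 10) return(fail("too few edge pixels in frame", edges))
  curves_px <- lapply(model_curves, function(cv) rbind3m(cv) / calib)
  # canonicalize: model coordinates are projection-plane mm and need not
  # overlap the canvas; shift their centroid to the frame center and fold
  # the shift into the returned transform
  all_px <- do.call(rbind, curves_px)
  t0 <- c((w - 1) / 2, (h - 1) / 2) - colMeans(all_px)
  curves_px <- lapply(curves_px, function(cv) sweep(cv, 2, -t0))
  model_img <- soft_distance_image(do.call(rbind, curves_px), w, h, dt_sigma)
  edge_img <- soft_distance_image(ep, w, h, dt_sigma)
  kp_model <- sift_keypoints(model_img)
  kp_frame <- sift_keypoints(edge_img)
  diagnostics$n_kp_model <- length(kp_model)
  diagnostics$n_kp_frame <- length(kp_frame)
  init <- rigid_transform2d()
  n_matches <- 0L
  if (length(kp_model) >= 1 && length(kp_frame) >= 2) {
    m <- tryCatch(match_features(kp_model, kp_frame, tau),
                  error = function(e) NULL)
    if (!is.null(m) && nrow(m$pairs) >= 2) {
      n_matches <- nrow(m$pairs)
      init <- tryCatch(
        estimate_initial_transform(m, keypoint_positions(kp_model),
                                   keypoint_positions(kp_frame)),
        error = function(e) rigid_transform2d())
    }
  }
  if (n_matches < 2) return(fail("fewer than 2 accepted SIFT matches", edges))
  src <- do.call(rbind, curves_px)
  init_rmse <- {
    nn <- cn_knn(ep, apply_rigid2d(init, src), 1)
    sqrt(mean(nn$dist^2))
  }
  fit <- tryCatch(icp_refine(src, ep, init, tol = icp_tol,
                             max_iter = icp_max_iter),
                  error = function(e) NULL)
  if (is.null(fit)) return(fail("ICP failed", edges))
  if (fit$rmse > 5 * max(init_rmse, 1e-12))
    return(fail("ICP diverged", edges))
  diagnostics$init_rmse_px <- init_rmse
  diagnostics$icp_iterations <- length(attr(fit, "trace"))
  # undo the canonicalization: full map is x -> R (x + t0) + t
  fit <- rigid_transform2d(fit$R, as.numeric(fit$R %*% t0) + fit$t, fit$rmse)
  structure(list(transform = fit, rmse_mm = fit$rmse * calib,
                 n_matches = n_matches, status = "ok", edges = edges,
                 diagnostics = diagnostics),
            class = "frame_registration")
}

#' @export
print.frame_registration <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("frame_registration: ok, rmse %.3f mm, %d matches\n",
                x$rmse_mm, x$n_matches))
  else
    cat(sprintf("frame_registration: failed (%s)\n",
                x$diagnostics$reason))
  invisible(x)
}

#' Write a registration result as JSON
#' @param reg A [register_frame()] result.
#' @param path Output JSON path.
#' @export
write_registration_json <- function(reg, path) {
  payload <- if (reg$status == "ok")
    list(R = unname(reg$transform$R), t = unname(reg$transform$t),
         rmse_mm = reg$rmse_mm, n_matches = reg$n_matches, status = "ok")
  else list(R = NULL, t = NULL, rmse_mm = NULL, n_matches = reg$n_matches,
            status = "failed")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
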