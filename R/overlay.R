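# Semi-transparent BH-grid overlay on arthroscopic frames, and
# frame-to-frame tracking.

#' Overlay rendering options
#'
#' @param alpha Blend weight in 0..1.
#' @param grid_color,footprint_color,boundary_color RGB triplets in 0..1.
#' @param line_width Line width (px; 1 = single-pixel lines).
#' @export
overlay_spec <- function(alpha = 0.5, grid_color = c(0, 1, 1),
                         footprint_color = c(1, 0, 0),
                         boundary_color = c(1, 0, 0), line_width = 1) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  list(alpha = alpha, grid_color = grid_color,
       footprint_color = footprint_color, boundary_color = boundary_color,
       line_width = line_width)
}

#' Project a BH grid into frame pixel coordinates
#'
#' Maps the grid axes, 4x4 cell lines, footprint point and any boundary
#' curves (e.g. the CLR) through a frame registration into pixel space.
#'
#' @param grid A [build_grid()] result (projection-plane mm).
#' @param f A [rigid_transform2d()] mapping model px to frame px.
#' @param calib mm per px.
#' @param boundary_curves Optional list of N x 2 mm curves to map along.
#' @param frame_size Optional c(height, width); if given, a `status`
#'   attribute warns when the projected grid lies entirely outside.
#' @return List with `cells`, `D_axis`, `H_axis`, `footprint`, `boundary`
#'   (all px).
#' @export
project_grid <- function(grid, f, calib = 0.1, boundary_curves = NULL,
                         frame_size = NULL) {
  mapf <- function(pts_mm) apply_rigid2d(f, rbind3m(pts_mm) / calib)
  out <- list(cells = lapply(grid$cells, mapf),
              D_axis = mapf(grid$D_axis),
              H_axis = mapf(grid$H_axis),
              footprint = mapf(grid$footprint)[1, ],
              boundary = lapply(boundary_curves %||% list(), mapf))
  if (!is.null(frame_size)) {
    all_pts <- do.call(rbind, c(out$cells, list(rbind(out$footprint))))
    inside <- any(all_pts[, 1] >= 0 & all_pts[, 1] < frame_size[2] &
                    all_pts[, 2] >= 0 & all_pts[, 2] < frame_size[1])
    attr(out, "status") <- if (inside) "ok" else "outside_frame"
    if (!inside) warning("projected grid lies entirely outside the frame")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blend_px <- function(img, px, color1, alpha) {
  if (nrow(px) == 0) return(img)
  if (length(dim(img)) == 3) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[px] <- (1 - alpha) * plane[px] + alpha * color1[ch]
      img[, , ch] <- plane
    }
  } else {
    gray <- sum(c(0.2126, 0.7152, 0.0722) * color1)
    img[px] <- (1 - alpha) * img[px] + alpha * gray
  }
  img
}

thicken <- function(px, lw, height, width) {
  if (lw <= 1 || nrow(px) == 0) return(px)
  r <- floor(lw / 2)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  out <- do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    cbind(px[, 1] + off$dy[i], px[, 2] + off$dx[i])))
  out <- out[out[, 1] >= 1 & out[, 1] <= height &
               out[, 2] >= 1 & out[, 2] <= width, , drop = FALSE]
  unique(out)
}

#' Render a semi-transparent overlay
#'
#' Rasterizes the projected lines (no anti-aliasing) and alpha-blends them
#' onto the frame: `out = (1 - alpha) * frame + alpha * color` on line
#' pixels; every other pixel is bit-identical to the input.
#'
#' @param frame Grayscale matrix or RGB array in 0..1.
#' @param projected A [project_grid()] result (or a list of polylines under
#'   `$cells`).
#' @param spec An [overlay_spec()].
#' @return Image of the same shape as `frame`.
#' @export
render_overlay <- function(frame, projected, spec = overlay_spec()) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  out <- frame
  gpx <- rasterize_polylines(projected$cells, w, h)
  gpx <- thicken(gpx, spec$line_width, h, w)
  out <- blend_px(out, gpx, spec$grid_color, spec$alpha)
  if (length(projected$boundary) > 0) {
    bpx <- rasterize_polylines(projected$boundary, w, h)
    bpx <- thicken(bpx, spec$line_width, h, w)
    out <- blend_px(out, bpx, spec$boundary_color, spec$alpha)
  }
  if (!is.null(projected$footprint)) {
    th <- seq(0, 2 * pi, length.out = 33)
    circ <- cbind(projected$footprint[1] + 3 * cos(th),
                  projected$footprint[2] + 3 * sin(th))
    fpx <- thicken(rasterize_polylines(list(circ), w, h), spec$line_width, h, w)
    out <- blend_px(out, fpx, spec$footprint_color, spec$alpha)
  }
  out
}

#' Track a frame sequence
#'
#' Registers each frame by ICP seeded with the previous frame's transform;
#' a full SIFT re-initialization ([register_frame()]) is triggered for the
#' first frame, after a failed frame, and whenever the ICP RMSE exceeds
#' twice the running median.
#'
#' @param frames List of grayscale frame matrices.
#' @param model_curves List of N x 2 mm model curves.
#' @param calib mm per px.
#' @param init_f Optional initial [rigid_transform2d()] (px); skips the
#'   first SIFT initialization.
#' @param icp_tol,icp_max_iter ICP controls.
#' @return List with `transforms` (per frame, possibly NULL) and `log`
#'   (data frame: frame, rmse_mm, status, reinit).
#' @export
track_frames <- function(frames, model_curves, calib = 0.1, init_f = NULL,
                         icp_tol = 1e-6, icp_max_iter = 50) {
  if (length(frames) < 1) stop("need at least one frame")
  src <- do.call(rbind, lapply(model_curves, function(cv) rbind3m(cv) / calib))
  prev <- init_f
  transforms <- vector("list", length(frames))
  log <- data.frame(frame = integer(0), rmse_mm = numeric(0),
                    status = character(0), reinit = logical(0))
  rmse_hist <- numeric(0)
  for (i in seq_along(frames)) {
    frame <- as_gray(frames[[i]])
    reinit <- FALSE
    tf <- NULL
    if (!is.null(prev)) {
      edges <- detect_edges(enhance(frame))
      ep <- edge_points(edges)
      if (nrow(ep) >= 3) {
        tf <- tryCatch(icp_refine(src, ep, prev, tol = icp_tol,
                                  max_iter = icp_max_iter),
                       error = function(e) NULL)
      }
      if (!is.null(tf) && length(rmse_hist) >= 2 &&
            tf$rmse > 2 * median(rmse_hist)) {
        tf <- NULL  # drifted: force re-initialization
      }
    }
    if (is.null(tf)) {
      reinit <- TRUE
      reg <- register_frame(frame, model_curves, calib)
      if (reg$status == "ok") tf <- reg$transform
    }
    if (is.null(tf)) {
      log <- rbind(log, data.frame(frame = i, rmse_mm = NA_real_,
                                   status = "failed", reinit = reinit))
      prev <- NULL
      next
    }
    transforms[[i]] <- tf
    rmse_hist <- c(rmse_hist, tf$rmse)
    prev <- tf
    log <- rbind(log, data.frame(frame = i, rmse_mm = tf$rmse * calib,
                                 status = "ok", reinit = reinit))
  }
  if (all(log$status == "failed")) stop("tracking failed on every frame")
  list(transforms = transforms, log = log)
}
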