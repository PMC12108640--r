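# Two-stage arthroscopic-to-model registration: adaptive histogram
# equalization, Canny edges, SIFT keypoints and ratio-test matching for the
# initial alignment, then 2D rigid ICP refinement.

#' Adaptive histogram equalization
#'
#' Tile-based contrast-limited adaptive histogram equalization (CLAHE) on
#' the luminance channel; the output is clamped to the input range.
#'
#' @param img Image matrix (or RGB array; converted to grayscale).
#' @param tiles Number of tiles per dimension.
#' @param limit Clip limit.
#' @return Enhanced grayscale matrix.
#' @export
enhance <- function(img, tiles = 8, limit = 2) {
  img <- as_gray(img)
  if (length(img) == 0) stop("empty image")
  rng <- range(img)
  if (diff(rng) < 1e-12) return(img)  # constant image: nothing to amplify
  h <- nrow(img); w <- ncol(img)
  # CLAHE tiles must divide the image; pad by edge replication, crop after
  hp <- ceiling(h / tiles) * tiles
  wp <- ceiling(w / tiles) * tiles
  padded <- img[pmin(seq_len(hp), h), pmin(seq_len(wp), w)]
  out <- EBImage::imageData(EBImage::clahe(EBImage::Image(t(padded)),
                                           nx = tiles, ny = tiles,
                                           limit = limit, keep.range = TRUE))
  out <- t(out)[seq_len(h), seq_len(w)]
  pmin(pmax(out, rng[1]), rng[2])
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis on the normalized gradient magnitude. Defaults are fixed at
#' sigma = 1.2 px with hysteresis thresholds 0.3 / 0.7. Normalization is
#' robust: magnitudes are scaled by the 99th percentile over the
#' non-maximum-suppression candidates (scaling by the absolute maximum
#' lets a single high-contrast silhouette suppress every anatomical edge).
#'
#' @param img Grayscale matrix in 0..1.
#' @param sigma Gaussian sigma (px).
#' @param t_low,t_high Hysteresis thresholds on normalized magnitude.
#' @return Logical edge mask.
#' @export
detect_edges <- function(img, sigma = 1.2, t_low = 0.3, t_high = 0.7) {
  img <- as_gray(img)
  sm <- gblur2(img, sigma)
  gx <- (shift2(sm, 0, -1) - shift2(sm, 0, 1)) / 2 +
    (shift2(sm, -1, -1) - shift2(sm, -1, 1)) / 4 +
    (shift2(sm, 1, -1) - shift2(sm, 1, 1)) / 4
  gy <- (shift2(sm, -1, 0) - shift2(sm, 1, 0)) / 2 +
    (shift2(sm, -1, -1) - shift2(sm, 1, -1)) / 4 +
    (shift2(sm, -1, 1) - shift2(sm, 1, 1)) / 4
  mag <- sqrt(gx^2 + gy^2)
  # suppress the shift-induced border response
  mag[c(1, 2, nrow(mag) - 1, nrow(mag)), ] <- 0
  mag[, c(1, 2, ncol(mag) - 1, ncol(mag))] <- 0
  if (max(mag) < 1e-12) return(matrix(FALSE, nrow(img), ncol(img)))
  # non-maximum suppression in 4 quantized gradient directions
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4
  n1 <- matrix(0, nrow(img), ncol(img))
  n2 <- n1
  sh <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (s in 0:3) {
    sel <- sector == s
    d <- sh[[s + 1]]
    a <- shift2(mag, d[1], d[2])
    b <- shift2(mag, -d[1], -d[2])
    n1[sel] <- a[sel]
    n2[sel] <- b[sel]
  }
  # ties broken asymmetrically so a plateau keeps a single-pixel line
  nms <- mag >= n1 & mag > n2 & mag > 0
  scale <- as.numeric(quantile(mag[nms], 0.99))
  if (scale < 1e-12) scale <- max(mag)
  mag <- pmin(mag / scale, 1)
  strong <- nms & mag >= t_high
  weak <- nms & mag >= t_low
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(EBImage::Image(t(weak)))
  lab <- t(as.matrix(lab))
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  weak & (lab %in% keep)
}

#' Edge pixel coordinates
#' @param mask Logical edge mask.
#' @return N x 2 matrix of 0-based (u, v) pixel positions.
#' @export
edge_points <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(u = idx[, 2] - 1, v = idx[, 1] - 1)
}

#' Rigid 2D transform
#'
#' @param R 2x2 rotation matrix (orthonormal, det +1).
#' @param t Translation 2-vector.
#' @param rmse Optional fit error (same units as the points).
#' @export
rigid_transform2d <- function(R = diag(2), t = c(0, 0), rmse = NA_real_) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(2))) > 1e-6 || det(R) < 0)
    stop("R must be a rotation matrix")
  structure(list(R = R, t = as.numeric(t), rmse = rmse),
            class = "rigid_transform2d")
}

#' Rotation-angle constructor for [rigid_transform2d()]
#' @param angle_deg Rotation angle (degrees, counter-clockwise in the
#'   x-right / y-down image frame).
#' @param t Translation 2-vector.
#' @export
rigid_from_angle <- function(angle_deg, t = c(0, 0)) {
  a <- deg2rad(angle_deg)
  rigid_transform2d(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2), t)
}

#' Apply a rigid 2D transform to points
#' @param tf A [rigid_transform2d()].
#' @param pts N x 2 matrix.
#' @export
apply_rigid2d <- function(tf, pts) {
  pts <- rbind3m(pts)
  sweep(pts %*% t(tf$R), 2, -tf$t)
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  ang <- rad2deg(atan2(x$R[2, 1], x$R[1, 1]))
  cat(sprintf("rigid_transform2d: rotation %.3f deg, t = (%.3f, %.3f), rmse %.4g\n",
              ang, x$t[1], x$t[2], x$rmse))
  invisible(x)
}

# Closed-form least-squares rigid fit (Kabsch/Procrustes, 2D).
kabsch2d <- function(src, dst) {
  cs <- colMeans(src)
  cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  t <- cd - as.numeric(R %*% cs)
  res <- sweep(src %*% t(R), 2, -t) - dst
  rigid_transform2d(R, t, sqrt(mean(rowSums(res^2))))
}

#' Initial transform from matched keypoints
#'
#' Least-squares rigid fit over the matched positions with greedy outlier
#' rejection: the worst-residual correspondence is dropped repeatedly until
#' the RMSE stabilizes (relative improvement below `stall`) or half the
#' matches are gone.
#'
#' @param matches A [match_features()] result.
#' @param a_pts,b_pts Keypoint position matrices (N x 2) for the two sets;
#'   the transform maps `a` positions onto `b` positions.
#' @param stall Relative RMSE improvement below which trimming stops.
#' @return A [rigid_transform2d()].
#' @export
estimate_initial_transform <- function(matches, a_pts, b_pts, stall = 0.01) {
  pr <- matches$pairs
  if (is.null(pr) || nrow(pr) < 2) stop("need at least 2 accepted matches")
  src <- rbind3m(a_pts)[pr[, 1], , drop = FALSE]
  dst <- rbind3m(b_pts)[pr[, 2], , drop = FALSE]
  keep <- seq_len(nrow(src))
  fit <- kabsch2d(src, dst)
  nmin <- max(2, ceiling(nrow(src) / 2))
  while (length(keep) > nmin) {
    res <- rowSums((apply_rigid2d(fit, src[keep, , drop = FALSE]) -
                      dst[keep, , drop = FALSE])^2)
    cand <- keep[-which.max(res)]
    fit2 <- kabsch2d(src[cand, , drop = FALSE], dst[cand, , drop = FALSE])
    if (fit$rmse - fit2$rmse < stall * max(fit$rmse, 1e-12)) break
    keep <- cand
    fit <- fit2
  }
  fit
}

#' Iterative closest point refinement (2D rigid)
#'
#' Alternates nearest-neighbour correspondence (kd-tree) with the
#' closed-form rigid update T = argmin sum |R x_i + t - y_i|^2, recording
#' the RMSE after each update; the sequence is non-increasing. Stops when
#' the RMSE change falls below `tol` or after `max_iter` iterations.
#'
#' @param source,target N x 2 point matrices (same units).
#' @param init Initial [rigid_transform2d()].
#' @param tol Absolute RMSE-change convergence threshold.
#' @param max_iter Iteration cap.
#' @param max_dist Optional correspondence distance cutoff.
#' @return A [rigid_transform2d()] with `rmse` and attribute `trace`
#'   (per-iteration RMSE).
#' @export
icp_refine <- function(source, target, init = rigid_transform2d(),
                       tol = 1e-6, max_iter = 100, max_dist = Inf) {
  source <- rbind3m(source)
  target <- rbind3m(target)
  if (nrow(source) < 3 || nrow(target) < 3) stop("need at least 3 points")
  sv <- svd(sweep(target, 2, colMeans(target)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300)) stop("target points are collinear")
  tf <- init
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    moved <- apply_rigid2d(tf, source)
    nn <- cn_knn(target, moved, 1)
    idx <- nn$idx[, 1]
    ok <- nn$dist[, 1] <= max_dist
    if (sum(ok) < 3) stop("too few correspondences under max_dist")
    upd <- kabsch2d(source[ok, , drop = FALSE], target[idx[ok], , drop = FALSE])
    res <- apply_rigid2d(upd, source[ok, , drop = FALSE]) -
      target[idx[ok], , drop = FALSE]
    rmse <- sqrt(mean(rowSums(res^2)))
    tf <- rigid_transform2d(upd$R, upd$t, rmse)
    trace <- c(trace, rmse)
    if (abs(prev - rmse) < tol) break
    prev <- rmse
  }
  attr(tf, "trace") <- trace
  tf
}
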