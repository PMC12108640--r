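# SIFT keypoint detection, description and ratio-test matching.
# Keypoints are found as scale-space extrema of the difference-of-Gaussians
# D(x, y, sigma) = L(x, y, k sigma) - L(x, y, sigma), with k = 2^(1/s),
# refined to sub-pixel accuracy, filtered by contrast and edge response,
# assigned gradient-histogram orientations, and described by 4x4x8 = 128
# Gaussian-weighted orientation histograms over a 16x16 sample
# neighbourhood, normalized to unit length.

#' Scale-space configuration
#'
#' @param n_octaves Number of octaves.
#' @param intervals Intervals per octave s (scales per octave); the scale
#'   factor between adjacent levels is k = 2^(1/s).
#' @param base_sigma Base blur sigma (px) of the first level.
#' @param contrast_thresh Minimum |DoG| response (per-interval normalized).
#' @param edge_thresh Principal-curvature ratio bound for edge rejection.
#' @export
scale_space_config <- function(n_octaves = 4, intervals = 3, base_sigma = 1.6,
                               contrast_thresh = 0.03, edge_thresh = 10) {
  if (intervals < 1) stop("intervals must be >= 1")
  list(n_octaves = n_octaves, intervals = intervals, base_sigma = base_sigma,
       k = 2^(1 / intervals), contrast_thresh = contrast_thresh,
       edge_thresh = edge_thresh)
}

# gradients of a blurred level
grad2 <- function(m) {
  list(gx = (shift2(m, 0, -1) - shift2(m, 0, 1)) / 2,
       gy = (shift2(m, -1, 0) - shift2(m, 1, 0)) / 2)
}

#' SIFT keypoints and descriptors
#'
#' @param img Grayscale matrix in 0..1, at least 32 x 32.
#' @param cfg A [scale_space_config()].
#' @return List of keypoints, each with `position` (0-based px, u/v),
#'   `scale` (px, in input-image units), `orientation` (rad) and
#'   `descriptor` (length-128 unit vector). May be empty.
#' @export
sift_keypoints <- function(img, cfg = scale_space_config()) {
  img <- as_gray(img)
  if (nrow(img) < 32 || ncol(img) < 32) stop("image must be at least 32x32")
  s <- cfg$intervals
  k <- cfg$k
  base <- img
  # assume input blur ~0.5 px; bring to base_sigma
  d0 <- sqrt(max(cfg$base_sigma^2 - 0.25, 0.01))
  base <- gblur2(base, d0)
  keypoints <- list()
  oct_scale <- 1
  for (o in seq_len(cfg$n_octaves)) {
    if (nrow(base) < 16 || ncol(base) < 16) break
    # Gaussian stack: s + 3 levels
    G <- vector("list", s + 3)
    G[[1]] <- base
    sig_prev <- cfg$base_sigma
    for (i in 2:(s + 3)) {
      sig_i <- cfg$base_sigma * k^(i - 1)
      G[[i]] <- gblur2(G[[i - 1]], sqrt(sig_i^2 - sig_prev^2))
      sig_prev <- sig_i
    }
    D <- lapply(1:(s + 2), function(i) G[[i + 1]] - G[[i]])
    h <- nrow(base); w <- ncol(base)
    for (i in 2:(s + 1)) {
      cur <- D[[i]]
      # 26-neighbour extremum masks, vectorized via shifts
      mx <- pmax(shift2(cur, -1, -1, -Inf), shift2(cur, -1, 0, -Inf),
                 shift2(cur, -1, 1, -Inf), shift2(cur, 0, -1, -Inf),
                 shift2(cur, 0, 1, -Inf), shift2(cur, 1, -1, -Inf),
                 shift2(cur, 1, 0, -Inf), shift2(cur, 1, 1, -Inf))
      mn <- -pmax(-shift2(cur, -1, -1, Inf), -shift2(cur, -1, 0, Inf),
                  -shift2(cur, -1, 1, Inf), -shift2(cur, 0, -1, Inf),
                  -shift2(cur, 0, 1, Inf), -shift2(cur, 1, -1, Inf),
                  -shift2(cur, 1, 0, Inf), -shift2(cur, 1, 1, Inf))
      for (dd in c(-1, 1)) {
        lay <- D[[i + dd]]
        for (dy in -1:1) for (dx in -1:1) {
          mx <- pmax(mx, shift2(lay, dy, dx, -Inf))
          mn <- pmin(mn, shift2(lay, dy, dx, Inf))
        }
      }
      pre <- abs(cur) > 0.5 * cfg$contrast_thresh / s
      is_ext <- pre & ((cur > mx) | (cur < mn))
      is_ext[c(1:8, (h - 7):h), ] <- FALSE
      is_ext[, c(1:8, (w - 7):w)] <- FALSE
      idx <- which(is_ext, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      sig_rel <- cfg$base_sigma * k^(i - 1)
      gr <- grad2(G[[i]])
      for (q in seq_len(nrow(idx))) {
        r <- idx[q, 1]; c0 <- idx[q, 2]
        # 3D quadratic refinement
        gvec <- c((cur[r, c0 + 1] - cur[r, c0 - 1]) / 2,
                  (cur[r + 1, c0] - cur[r - 1, c0]) / 2,
                  (D[[i + 1]][r, c0] - D[[i - 1]][r, c0]) / 2)
        dxx <- cur[r, c0 + 1] + cur[r, c0 - 1] - 2 * cur[r, c0]
        dyy <- cur[r + 1, c0] + cur[r - 1, c0] - 2 * cur[r, c0]
        dss <- D[[i + 1]][r, c0] + D[[i - 1]][r, c0] - 2 * cur[r, c0]
        dxy <- (cur[r + 1, c0 + 1] - cur[r + 1, c0 - 1] -
                  cur[r - 1, c0 + 1] + cur[r - 1, c0 - 1]) / 4
        dxs <- (D[[i + 1]][r, c0 + 1] - D[[i + 1]][r, c0 - 1] -
                  D[[i - 1]][r, c0 + 1] + D[[i - 1]][r, c0 - 1]) / 4
        dys <- (D[[i + 1]][r + 1, c0] - D[[i + 1]][r - 1, c0] -
                  D[[i - 1]][r + 1, c0] + D[[i - 1]][r - 1, c0]) / 4
        H3 <- matrix(c(dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss), 3, 3)
        off <- tryCatch(-solve(H3, gvec), error = function(e) c(0, 0, 0))
        if (any(!is.finite(off)) || max(abs(off)) > 1.5) off <- c(0, 0, 0)
        peak <- cur[r, c0] + 0.5 * sum(gvec * off)
        if (abs(peak) < cfg$contrast_thresh / s) next
        # edge response rejection on the 2x2 spatial Hessian
        tr <- dxx + dyy
        det2 <- dxx * dyy - dxy^2
        et <- cfg$edge_thresh
        if (det2 <= 0 || tr^2 / det2 >= (et + 1)^2 / et) next
        u <- (c0 - 1) + off[1]
        v <- (r - 1) + off[2]
        # orientation histogram (36 bins) over a Gaussian window
        sig_w <- 1.5 * sig_rel
        rad <- max(3L, round(3 * sig_w))
        rr <- max(1, r - rad):min(h, r + rad)
        cc <- max(1, c0 - rad):min(w, c0 + rad)
        gx <- gr$gx[rr, cc]; gy <- gr$gy[rr, cc]
        mag <- sqrt(gx^2 + gy^2)
        dy <- outer(rr - r, rep(1, length(cc)))
        dx <- outer(rep(1, length(rr)), cc - c0)
        wgt <- exp(-(dx^2 + dy^2) / (2 * sig_w^2)) * mag
        ang <- atan2(gy, gx) %% (2 * pi)
        bins <- floor(ang / (2 * pi) * 36) %% 36
        hist36 <- vapply(0:35, function(b) sum(wgt[bins == b]), numeric(1))
        for (pass in 1:2)  # circular smoothing
          hist36 <- (hist36 + c(tail(hist36, 1), head(hist36, -1)) +
                       c(tail(hist36, -1), head(hist36, 1))) / 3
        pk <- max(hist36)
        if (pk <= 0) next
        for (b in which(hist36 >= 0.8 * pk)) {
          b_prev <- hist36[(b - 2) %% 36 + 1]
          b_next <- hist36[b %% 36 + 1]
          if (hist36[b] < b_prev || hist36[b] < b_next) next
          denom <- b_prev - 2 * hist36[b] + b_next
          shift_b <- if (abs(denom) > 1e-12)
            0.5 * (b_prev - b_next) / denom else 0
          ori <- ((b - 1 + 0.5 + shift_b) / 36) * 2 * pi
          desc <- sift_descriptor(G[[i]], gr, u, v, ori, sig_rel)
          if (is.null(desc)) next
          keypoints[[length(keypoints) + 1]] <- list(
            position = c(u = u * oct_scale, v = v * oct_scale),
            scale = sig_rel * oct_scale,
            orientation = ori,
            octave = o,
            descriptor = desc)
        }
      }
    }
    # next octave: downsample the level with sigma = 2 * base_sigma
    base <- G[[s + 1]][seq(1, nrow(base), by = 2), seq(1, ncol(base), by = 2)]
    oct_scale <- oct_scale * 2
  }
  keypoints
}

# 4x4x8 orientation-histogram descriptor over a rotated 16x16 sample grid
# (sample spacing = the keypoint's per-octave scale), Gaussian-weighted,
# trilinearly binned, normalized / clamped at 0.2 / renormalized.
sift_descriptor <- function(G, gr, u, v, ori, sig_rel) {
  nspatial <- 4
  nori <- 8
  spacing <- sig_rel
  co <- cos(ori); si <- sin(ori)
  grid <- seq(-7.5, 7.5, by = 1)
  gg <- expand.grid(gx = grid, gy = grid)
  # rotate sample offsets by the keypoint orientation
  su <- u + spacing * (co * gg$gx - si * gg$gy)
  sv <- v + spacing * (si * gg$gx + co * gg$gy)
  gxv <- bilinear_sample(gr$gx, su, sv)
  gyv <- bilinear_sample(gr$gy, su, sv)
  ok <- !is.na(gxv) & !is.na(gyv)
  if (sum(ok) < 64) return(NULL)
  mag <- sqrt(gxv^2 + gyv^2)
  ang <- (atan2(gyv, gxv) - ori) %% (2 * pi)
  wgt <- exp(-(gg$gx^2 + gg$gy^2) / (2 * 8^2)) * mag
  # trilinear binning into (4 x 4 spatial) x (8 orientation)
  xc <- (gg$gx + 8) / 4 - 0.5   # in [-0.5, 3.5]
  yc <- (gg$gy + 8) / 4 - 0.5
  oc <- ang / (2 * pi) * nori
  desc <- numeric(nspatial * nspatial * nori)
  x0 <- floor(xc); y0 <- floor(yc); o0 <- floor(oc)
  fx <- xc - x0; fy <- yc - y0; fo <- oc - o0
  for (dx in 0:1) for (dy in 0:1) for (do in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; oi <- (o0 + do) %% nori
    wq <- wgt * (dx * fx + (1 - dx) * (1 - fx)) *
      (dy * fy + (1 - dy) * (1 - fy)) *
      (do * fo + (1 - do) * (1 - fo))
    val <- ok & xi >= 0 & xi <= 3 & yi >= 0 & yi <= 3
    if (!any(val)) next
    bin <- (yi * nspatial + xi) * nori + oi + 1
    add <- rowsum(wq[val], bin[val])
    desc[as.integer(rownames(add))] <- desc[as.integer(rownames(add))] + add
  }
  nrm <- sqrt(sum(desc^2))
  if (nrm < 1e-12) return(NULL)
  desc <- desc / nrm
  desc <- pmin(desc, 0.2)
  desc / sqrt(sum(desc^2))
}

#' Descriptor matrix of a keypoint list
#' @param kps List from [sift_keypoints()].
#' @return N x 128 matrix.
#' @export
keypoint_descriptors <- function(kps) {
  if (length(kps) == 0) return(matrix(numeric(0), 0, 128))
  do.call(rbind, lapply(kps, function(k) k$descriptor))
}

#' Keypoint positions
#' @param kps List from [sift_keypoints()].
#' @return N x 2 matrix of 0-based (u, v) px.
#' @export
keypoint_positions <- function(kps) {
  if (length(kps) == 0) return(matrix(numeric(0), 0, 2))
  do.call(rbind, lapply(kps, function(k) unname(k$position)))
}

#' Ratio-test feature matching
#'
#' For each descriptor in `a`, the nearest and second-nearest neighbours in
#' `b` are found with an exact kd-tree search; a match is accepted when the
#' distance ratio ||p - q1|| / ||p - q2|| is below `tau` (0.75).
#'
#' @param a,b Keypoint lists (from [sift_keypoints()]) or descriptor
#'   matrices.
#' @param tau Ratio-test threshold.
#' @return List of class `match_set`: `pairs` (index_a, index_b, ratio
#'   columns) and `tau`.
#' @export
match_features <- function(a, b, tau = 0.75) {
  da <- if (is.matrix(a)) a else keypoint_descriptors(a)
  db <- if (is.matrix(b)) b else keypoint_descriptors(b)
  if (nrow(da) == 0) stop("empty descriptor set a")
  if (nrow(db) < 2) stop("need at least 2 descriptors in b for the ratio test")
  nn <- cn_knn(db, da, 2)
  ratio <- nn$dist[, 1] / pmax(nn$dist[, 2], 1e-300)
  acc <- which(ratio < tau)
  pairs <- cbind(index_a = acc, index_b = nn$idx[acc, 1],
                 ratio = ratio[acc])
  structure(list(pairs = pairs, tau = tau), class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("match_set: %d accepted pairs (tau = %.2f)\n",
              nrow(x$pairs), x$tau))
  invisible(x)
}
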