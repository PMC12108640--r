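# Initial sagittal plane from intercondylar-notch landmarks, and
# plane-mesh intersection contours.

#' Initial sagittal plane from notch landmarks
#'
#' The plane contains the two reference points picked along the central line
#' of the intercondylar notch (anterior and posterior margin) and is
#' perpendicular to the transverse plane of the distal femur, thereby
#' dividing the medial and lateral condyles.
#'
#' @param anterior_pt,posterior_pt 3-points (mm) on the notch central line.
#' @param transverse_normal Normal of the transverse plane (unit 3-vector);
#'   the sagittal plane contains this direction.
#' @param medial_point Optional 3-point on the medial side; when given, the
#'   plane normal is oriented towards it.
#' @return A [plane()].
#' @export
initial_sagittal_plane <- function(anterior_pt, posterior_pt,
                                   transverse_normal = c(0, 0, 1),
                                   medial_point = NULL) {
  a <- as.numeric(anterior_pt)
  p <- as.numeric(posterior_pt)
  d <- a - p
  if (vnorm(d) < 1e-9) stop("notch landmarks coincide")
  n <- cross3(unitize(transverse_normal), d)
  if (vnorm(n) < 1e-9 * vnorm(d))
    stop("notch landmarks differ only along the transverse normal")
  pl <- plane(n, point = p)
  if (!is.null(medial_point) && plane_distance(pl, medial_point) < 0)
    pl <- plane(-pl$normal, -pl$offset)
  pl
}

#' Read sagittal-plane landmarks from JSON
#'
#' Expected fields: `anterior_notch`, `posterior_notch` (mm 3-vectors) and
#' optionally `transverse_normal` (default scanner z) and `medial_point`.
#'
#' @param path JSON file path.
#' @return Named list of landmark vectors.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::fromJSON(path)
  if (is.null(lm$anterior_notch) || is.null(lm$posterior_notch))
    stop("landmarks file must contain anterior_notch and posterior_notch")
  if (is.null(lm$transverse_normal)) lm$transverse_normal <- c(0, 0, 1)
  lm
}

#' Planar contour
#'
#' Ordered 2D points (mm) in an in-plane orthonormal frame.
#'
#' @param points N x 2 matrix.
#' @param frame An in-plane frame as from [plane_frame()].
#' @param closed Logical; closed loops have at least 3 points.
#' @return Object of class `planar_contour`.
#' @export
planar_contour <- function(points, frame, closed = FALSE) {
  points <- as.matrix(points)
  if (closed && nrow(points) < 3) stop("closed contours need >= 3 points")
  structure(list(points = points, frame = frame, closed = closed),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("planar_contour: %d points (%s)\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' 3D coordinates of a contour
#' @param contour A [planar_contour()].
#' @return N x 3 matrix (mm).
#' @export
contour_points_3d <- function(contour) from_plane_2d(contour$frame, contour$points)

contour_arclengths <- function(pts, closed = FALSE) {
  if (closed) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

polygon_area_signed <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  i2 <- c(seq_len(nrow(pts))[-1], 1)
  0.5 * sum(x * y[i2] - x[i2] * y)
}

#' Intersect a mesh with a plane
#'
#' Links all edge-plane crossings of the triangulation into ordered
#' polylines; closed loops are oriented counter-clockwise in the in-plane
#' frame. Contours are returned largest-first by absolute enclosed area
#' (open polylines by length).
#'
#' @param mesh A [surface_mesh()].
#' @param pl A [plane()].
#' @param frame Optional in-plane frame (default [plane_frame()] of `pl`).
#' @return List of [planar_contour()] (empty if no intersection).
#' @export
plane_mesh_contour <- function(mesh, pl, frame = NULL) {
  if (is.null(frame)) frame <- plane_frame(pl)
  V <- mesh$vertices
  F <- mesh$faces
  d <- plane_distance(pl, V)
  side <- d >= 0
  fs <- cbind(side[F[, 1]], side[F[, 2]], side[F[, 3]])
  ncross <- rowSums(fs)
  hit <- ncross == 1 | ncross == 2
  if (!any(hit)) return(list())
  Fh <- F[hit, , drop = FALSE]

  edge_cross <- function(a, b) {
    # interpolation point on crossing edges; key canonical by vertex ids
    da <- d[a]; db <- d[b]
    t <- da / (da - db)
    p <- V[a, , drop = FALSE] + t * (V[b, , drop = FALSE] - V[a, , drop = FALSE])
    list(key = paste(pmin(a, b), pmax(a, b)), p = p)
  }
  segs_key <- vector("list", nrow(Fh))
  # for each face, the two crossed edges
  ek <- matrix("", nrow(Fh), 2)
  ep <- array(NA_real_, c(nrow(Fh), 2, 3))
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  cnt <- rep(0L, nrow(Fh))
  for (pr in pairs) {
    a <- Fh[, pr[1]]; b <- Fh[, pr[2]]
    crossing <- xor(side[a], side[b])
    if (!any(crossing)) next
    ec <- edge_cross(a[crossing], b[crossing])
    rows <- which(crossing)
    slot <- cnt[rows] + 1L
    for (i in seq_along(rows)) {
      ek[rows[i], slot[i]] <- ec$key[i]
      ep[rows[i], slot[i], ] <- ec$p[i, ]
    }
    cnt[rows] <- slot
  }
  ok <- cnt == 2L
  ek <- ek[ok, , drop = FALSE]
  ep <- ep[ok, , , drop = FALSE]
  if (nrow(ek) == 0) return(list())

  # link segments: adjacency between edge keys
  keys <- unique(as.vector(ek))
  kid <- setNames(seq_along(keys), keys)
  k1 <- kid[ek[, 1]]; k2 <- kid[ek[, 2]]
  pos <- matrix(NA_real_, length(keys), 3)
  pos[k1, ] <- ep[, 1, ]
  pos[k2, ] <- ep[, 2, ]
  nseg <- length(k1)
  adj <- vector("list", length(keys))
  for (i in seq_len(nseg)) {
    adj[[k1[i]]] <- c(adj[[k1[i]]], i)
    adj[[k2[i]]] <- c(adj[[k2[i]]], i)
  }
  used <- rep(FALSE, nseg)
  contours <- list()
  other_end <- function(s, k) if (k1[s] == k) k2[s] else k1[s]
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    # walk both directions from segment s0
    chain <- c(k1[s0], k2[s0])
    used[s0] <- TRUE
    repeat { # forward
      kend <- chain[length(chain)]
      nxt <- setdiff(adj[[kend]][!used[adj[[kend]]]], integer(0))
      if (length(nxt) == 0) break
      s <- nxt[1]
      used[s] <- TRUE
      kn <- other_end(s, kend)
      if (kn == chain[1]) { chain <- c(chain, kn); break }
      chain <- c(chain, kn)
    }
    closed <- chain[1] == chain[length(chain)] && length(chain) > 3
    if (closed) {
      chain <- chain[-length(chain)]
    } else {
      repeat { # backward
        kstart <- chain[1]
        nxt <- adj[[kstart]][!used[adj[[kstart]]]]
        if (length(nxt) == 0) break
        s <- nxt[1]
        used[s] <- TRUE
        chain <- c(other_end(s, kstart), chain)
      }
    }
    pts3 <- pos[chain, , drop = FALSE]
    pts2 <- to_plane_2d(frame, pts3)
    # drop consecutive duplicates
    if (nrow(pts2) > 1) {
      dup <- c(FALSE, rowSums(abs(diff(pts2)))/2 < 1e-12)
      pts2 <- pts2[!dup, , drop = FALSE]
    }
    if (closed && nrow(pts2) >= 3 && polygon_area_signed(pts2) < 0)
      pts2 <- pts2[rev(seq_len(nrow(pts2))), , drop = FALSE]
    if (nrow(pts2) >= 2)
      contours[[length(contours) + 1]] <- planar_contour(pts2, frame, closed)
  }
  size <- vapply(contours, function(ct) {
    if (ct$closed) abs(polygon_area_signed(ct$points))
    else max(contour_arclengths(ct$points))
  }, numeric(1))
  contours[order(size, decreasing = TRUE)]
}
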