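# 2D image utilities. Images are numeric matrices [row = y, col = x] with
# values in [0, 1]; pixel coordinates are 0-based (u = x = col - 1,
# v = y = row - 1), origin top-left, x right, y down.

#' Read a PNG image as a grayscale matrix
#' @param path PNG file path.
#' @return Numeric matrix in 0..1.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  as_gray(img)
}

#' Write a matrix (or RGB array) as PNG
#' @param img Matrix or array with values in 0..1.
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Convert an image to grayscale
#' @param img Matrix or h x w x 3 array.
#' @return Numeric matrix.
#' @export
as_gray <- function(img) {
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img <- img[, , 1]
  }
  img
}

# matrix shift (rows dy, cols dx), zero fill
shift2 <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Gaussian blur via EBImage (transposed: EBImage images are x,y); falls
# back to a separable R implementation when the kernel exceeds the image.
gblur2 <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (2 * ceiling(3 * sigma) + 1 <= min(dim(img)))
    return(t(as.matrix(EBImage::gblur(EBImage::Image(t(img)), sigma = sigma,
                                      boundary = "replicate"))))
  r <- ceiling(3 * sigma)
  kv <- exp(-((-r:r)^2) / (2 * sigma^2))
  conv1 <- function(m) {  # along rows (y)
    acc <- matrix(0, nrow(m), ncol(m))
    nrm <- acc
    ones <- matrix(1, nrow(m), ncol(m))
    for (q in -r:r) {
      acc <- acc + kv[q + r + 1] * shift2(m, q, 0)
      nrm <- nrm + kv[q + r + 1] * shift2(ones, q, 0)
    }
    acc / nrm
  }
  t(conv1(t(conv1(img))))
}

# Bilinear sampling at 0-based (u, v) positions; outside -> NA
bilinear_sample <- function(img, u, v) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(u); y0 <- floor(v)
  fx <- u - x0; fy <- v - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 2 & y0 <= h - 2
  out <- rep(NA_real_, length(u))
  if (!any(ok)) return(out)
  i <- y0[ok] + 1; j <- x0[ok] + 1
  fxo <- fx[ok]; fyo <- fy[ok]
  out[ok] <- img[cbind(i, j)] * (1 - fxo) * (1 - fyo) +
    img[cbind(i, j + 1)] * fxo * (1 - fyo) +
    img[cbind(i + 1, j)] * (1 - fxo) * fyo +
    img[cbind(i + 1, j + 1)] * fxo * fyo
  out
}

# Inverse-warp an image by a 2D rigid/affine map (0-based px coords):
# dst(v,u) = src at A %*% (u,v) + b.
warp_image <- function(img, A, b, width = ncol(img), height = nrow(img)) {
  uv <- as.matrix(expand.grid(u = 0:(width - 1), v = 0:(height - 1)))
  src <- uv %*% t(A) + matrix(b, nrow(uv), 2, byrow = TRUE)
  val <- bilinear_sample(img, src[, 1], src[, 2])
  val[is.na(val)] <- 0
  matrix(val, height, width, byrow = TRUE)
}

# Integer line rasterization of polylines (0-based px coords).
# Returns a two-column matrix of (row, col) 1-based pixel indices.
rasterize_polylines <- function(lines, width, height) {
  px <- list()
  for (L in lines) {
    L <- rbind3m(L)
    if (nrow(L) < 2) next
    for (i in seq_len(nrow(L) - 1)) {
      p0 <- L[i, ]; p1 <- L[i + 1, ]
      nstep <- max(abs(p1 - p0)) + 1
      n <- max(2L, ceiling(nstep))
      u <- round(seq(p0[1], p1[1], length.out = n))
      v <- round(seq(p0[2], p1[2], length.out = n))
      px[[length(px) + 1]] <- cbind(v + 1, u + 1)
    }
  }
  if (length(px) == 0) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, px)
  m <- m[m[, 1] >= 1 & m[, 1] <= height & m[, 2] >= 1 & m[, 2] <= width, ,
         drop = FALSE]
  unique(m)
}

# Soft distance-transform image: exp(-d / sigma) with d the distance of
# each pixel to the nearest of the given 0-based (u, v) points.
soft_distance_image <- function(pts, width, height, sigma) {
  pts <- rbind3m(pts)
  gridp <- as.matrix(expand.grid(u = 0:(width - 1), v = 0:(height - 1)))
  nn <- cn_knn(pts, gridp, 1)
  matrix(exp(-nn$dist[, 1] / sigma), height, width, byrow = TRUE)
}

# Render polylines into a blank image (value 1 on lines).
curves_to_image <- function(lines, width, height, blur = 0) {
  img <- matrix(0, height, width)
  px <- rasterize_polylines(lines, width, height)
  if (nrow(px) > 0) img[px] <- 1
  if (blur > 0) img <- gblur2(img, blur)
  img
}
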