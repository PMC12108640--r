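# Enhancement, edge detection, SIFT, matching, initial fit and ICP.

test_that("adaptive equalization preserves range and does not reduce entropy", {
  expect_identical(enhance(matrix(0.5, 64, 64)), matrix(0.5, 64, 64))
  # low-contrast textured image with a peaked histogram
  img <- 0.45 + 0.1 * textured_image(64, seed = 8)^2
  out <- enhance(img)
  expect_gte(min(out), min(img) - 1e-12)
  expect_lte(max(out), max(img) + 1e-12)
  entropy <- function(x) {  # fixed absolute bins over [0, 1]
    h <- tabulate(pmin(512L, 1L + floor(x * 512)), 512)
    p <- h[h > 0] / sum(h)
    -sum(p * log(p))
  }
  expect_gte(entropy(out), entropy(img) - 1e-9)
  expect_error(enhance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("edge detection finds a single-pixel step edge and nothing on constants", {
  expect_identical(sum(detect_edges(matrix(0.7, 64, 64))), 0L)
  step <- matrix(rep(c(rep(0, 32), rep(1, 32)), each = 64), 64, 64)
  es <- detect_edges(step)
  hits <- which(es, arr.ind = TRUE)
  expect_identical(sort(unique(hits[, 2])), 32L)   # one 1-px column
  expect_gt(nrow(hits), 50)                        # a connected vertical line
})

test_that("most projected crease pixels lie on detected edges of a rendered frame", {
  sc <- rendered_scene()
  edges <- detect_edges(enhance(sc$frame$image))
  ep <- edge_points(edges)
  d <- cn_knn_dist(ep, sc$frame$projected_crease)
  expect_gte(mean(d <= 2), 0.8)
})

test_that("SIFT descriptors are 128-long unit vectors; blank images give none", {
  expect_length(sift_keypoints(matrix(0.5, 64, 64)), 0)
  expect_error(sift_keypoints(matrix(0.5, 16, 16)), "32")
  kp <- sift_keypoints(textured_image())
  expect_gt(length(kp), 50)
  for (k in kp[1:10]) {
    expect_length(k$descriptor, 128)
    expect_equal(sqrt(sum(k$descriptor^2)), 1, tolerance = 1e-9)
  }
})

test_that("keypoints repeat under a 30-degree rotation", {
  img <- textured_image()
  kp <- sift_keypoints(img)
  th <- 30 * pi / 180
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(95.5, 95.5)
  b <- as.numeric(ctr - A %*% ctr)
  rot <- condylenav:::warp_image(img, A, b)
  kp2 <- sift_keypoints(rot)
  P <- keypoint_positions(kp)
  P2 <- keypoint_positions(kp2)
  Pd <- t(solve(A) %*% (t(P) - b))   # predicted positions in rotated image
  inb <- Pd[, 1] >= 10 & Pd[, 1] <= 181 & Pd[, 2] >= 10 & Pd[, 2] <= 181
  d <- cn_knn_dist(P2, Pd[inb, , drop = FALSE])
  expect_gte(mean(d < 3), 0.5)
  # matching across the rotation recovers the transform
  m <- match_features(kp, kp2)
  expect_gt(nrow(m$pairs), 20)
  tf <- estimate_initial_transform(m, P, P2)
  ang <- atan2(tf$R[2, 1], tf$R[1, 1]) * 180 / pi
  expect_lt(abs(ang + 30), 0.5)
})

test_that("the ratio test applies the 0.75 threshold to constructed distances", {
  # query at the origin; nearest at 0.6, second-nearest at 1.0 -> accept
  q <- matrix(0, 1, 128)
  b <- rbind(c(0.6, rep(0, 127)), c(0, 1, rep(0, 126)))
  m <- match_features(q, b, tau = 0.75)
  expect_identical(nrow(m$pairs), 1L)
  expect_equal(unname(m$pairs[1, "ratio"]), 0.6, tolerance = 1e-12)
  # nearest 0.8, second 1.0 -> rejected
  b2 <- rbind(c(0.8, rep(0, 127)), c(0, 1, rep(0, 126)))
  m2 <- match_features(q, b2, tau = 0.75)
  expect_identical(nrow(m2$pairs), 0L)
  # self-matching distinct descriptors: ratio ~ 0
  d <- withr::with_seed(3, matrix(runif(20 * 128), 20, 128))
  m3 <- match_features(d, d)
  expect_identical(nrow(m3$pairs), 20L)
  expect_identical(unname(m3$pairs[, "index_b"]),
                   as.numeric(m3$pairs[, "index_a"]))
  expect_error(match_features(d, d[1, , drop = FALSE]), "2 descriptors")
})

test_that("kd-tree matching equals exhaustive search on random descriptors", {
  da <- withr::with_seed(9, matrix(runif(200 * 16), 200, 16))
  db <- withr::with_seed(10, matrix(runif(500 * 16), 500, 16))
  nn <- condylenav:::cn_knn(db, da, 2)
  # brute force oracle
  for (i in seq(1, 200, by = 7)) {
    d <- sqrt(colSums((t(db) - da[i, ])^2))
    ord <- order(d)[1:2]
    expect_identical(nn$idx[i, ], ord)
    expect_equal(nn$dist[i, ], d[ord], tolerance = 1e-12)
  }
  m_tree <- match_features(da, db, tau = 0.9)
  ratio_bf <- vapply(seq_len(200), function(i) {
    d <- sort(sqrt(colSums((t(db) - da[i, ])^2)))[1:2]
    d[1] / d[2]
  }, numeric(1))
  expect_identical(as.integer(m_tree$pairs[, "index_a"]),
                   which(ratio_bf < 0.9))
})

test_that("initial transform survives gross outliers", {
  set.seed(21)
  src <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  tf_true <- rigid_from_angle(15, c(10, 5))
  dst <- apply_rigid2d(tf_true, src)
  # exact: recovered to machine precision
  m <- list(pairs = cbind(index_a = 1:50, index_b = 1:50, ratio = 0))
  fit <- estimate_initial_transform(m, src, dst)
  expect_rigid_close(fit, 15, c(10, 5), tol_angle = 1e-6, tol_t = 1e-6)
  # identity correspondence
  fit0 <- estimate_initial_transform(m, src, src)
  expect_rigid_close(fit0, 0, c(0, 0), tol_angle = 1e-9, tol_t = 1e-9)
  expect_lt(fit0$rmse, 1e-12)
  # 20% gross outliers
  dst2 <- dst
  out_idx <- 1:10
  dst2[out_idx, ] <- dst2[out_idx, ] + matrix(runif(20, 30, 60), 10, 2)
  fit2 <- estimate_initial_transform(m, src, dst2)
  ang <- atan2(fit2$R[2, 1], fit2$R[1, 1]) * 180 / pi
  expect_lt(abs(ang - 15), 1)
  expect_error(estimate_initial_transform(
    list(pairs = cbind(1, 1, 0)), src, dst), "2 accepted")
})

test_that("ICP recovers known rigid transforms with a monotone error trace", {
  set.seed(5)
  src <- cbind(runif(200, 0, 50), runif(200, 0, 30))
  # identity case
  f0 <- icp_refine(src, src, rigid_transform2d())
  expect_lt(f0$rmse, 1e-12)
  expect_rigid_close(f0, 0, c(0, 0), 1e-9, 1e-9)
  # noiseless known transform from a rough initialization
  tf_true <- rigid_from_angle(10, c(2, 1))
  dst <- apply_rigid2d(tf_true, src)
  init <- rigid_from_angle(18, c(0, 0))
  fit <- icp_refine(src, dst, init)
  expect_lt(fit$rmse, 1e-6)
  expect_rigid_close(fit, 10, c(2, 1), tol_angle = 1e-3, tol_t = 1e-3)
  expect_true(all(diff(attr(fit, "trace")) <= 1e-12))
  # degenerate target
  expect_error(icp_refine(src, cbind(1:10, 2 * (1:10)), rigid_transform2d()),
               "collinear")
})

test_that("registration is equivariant: pre-rotating the target rotates the result", {
  set.seed(6)
  src <- cbind(runif(300, 0, 40), runif(300, 0, 40))
  tf <- rigid_from_angle(5, c(1, -2))
  dst <- apply_rigid2d(tf, src)
  S <- rigid_from_angle(12, c(4, 3))
  dst2 <- apply_rigid2d(S, dst)
  f1 <- icp_refine(src, dst, rigid_transform2d())
  f2 <- icp_refine(src, dst2, rigid_from_angle(17, c(5, 1)))
  comp_R <- S$R %*% f1$R
  comp_t <- as.numeric(S$R %*% f1$t) + S$t
  expect_lt(max(abs(f2$R - comp_R)), 1e-3)
  expect_lt(max(abs(f2$t - comp_t)), 1e-2)
})
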