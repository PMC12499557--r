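test_that("ray geometry covers the circle with increasing angles", {
  g <- star_geometry(32)
  expect_equal(g$n_rays, 32L)
  expect_equal(g$angles[1], 0)
  expect_true(all(diff(g$angles) > 0))
  expect_lt(max(g$angles), 2 * pi)
  expect_error(star_geometry(2))
})

test_that("radial distance targets match the ray-marching oracle exactly", {
  geom <- star_geometry(8)
  for (seed in 1:6) {
    lab <- random_blob_mask(36, 36, n_obj = 4, seed = seed)
    expect_identical(star_distance_targets(lab, geom),
                     star_dist_oracle(lab, geom$angles))
  }
  # disc of radius 10: all 32 center distances within the discretization
  # band [9, 11]
  lab2 <- matrix(0L, 25, 25)
  lab2[(row(lab2) - 13)^2 + (col(lab2) - 13)^2 <= 100] <- 1L
  d <- star_distance_targets(lab2, star_geometry(32))
  expect_true(all(d[13, 13, ] >= 9 & d[13, 13, ] <= 11))
  # single-pixel object: distance 1 on every ray (unit-step convention)
  lab3 <- matrix(0L, 9, 9); lab3[5, 5] <- 1L
  expect_true(all(star_distance_targets(lab3, geom)[5, 5, ] == 1))
  # background pixels all zero
  expect_true(all(d[lab2 == 0L] == 0))
})

test_that("object probability targets are per-object normalized EDT", {
  lab2 <- matrix(0L, 25, 25)
  lab2[(row(lab2) - 13)^2 + (col(lab2) - 13)^2 <= 100] <- 1L
  pt <- object_probability_targets(lab2)
  expect_equal(max(pt), 1)
  expect_equal(pt[13, 13], 1)             # unique max at the disc center
  expect_equal(sum(pt == 1), 1)
  expect_true(all(pt[lab2 == 0] == 0))
  # independent oracle: EDT via scaled distance to nearest background
  edt <- matrix(0, 25, 25)
  bg <- which(lab2 == 0L, arr.ind = TRUE)
  for (ix in which(lab2 == 1L)) {
    i <- (ix - 1) %% 25 + 1; j <- (ix - 1) %/% 25 + 1
    edt[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  }
  expect_equal(pt[lab2 == 1L], (edt / max(edt))[lab2 == 1L],
               tolerance = 1e-10)
  # two objects: each attains 1; single-pixel object has probability 1
  lab <- matrix(0L, 20, 20)
  lab[4:8, 4:8] <- 1L; lab[15, 15] <- 2L
  p2 <- object_probability_targets(lab)
  expect_equal(max(p2[lab == 1L]), 1)
  expect_equal(p2[15, 15], 1)
})

test_that("star polygons rendered from targets reproduce convex objects", {
  # target consistency: polygon at each high-prob pixel, intersected with
  # the object, covers >= 95% of the object's area
  lab <- matrix(0L, 40, 40)
  lab[(row(lab) - 15)^2 / 81 + (col(lab) - 20)^2 / 36 <= 1] <- 1L
  geom <- star_geometry(32)
  d <- star_distance_targets(lab, geom)
  pt <- object_probability_targets(lab)
  ctr <- which(pt == max(pt), arr.ind = TRUE)[1, ]
  radii <- d[ctr[1], ctr[2], ]
  vy <- ctr[1] + radii * sin(geom$angles)
  vx <- ctr[2] + radii * cos(geom$angles)
  inside <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    wn <- FALSE
    n <- length(vy)
    for (a in seq_len(n)) {
      b <- if (a == n) 1L else a + 1L
      if ((vy[a] > i) != (vy[b] > i) &&
          j < (vx[b] - vx[a]) * (i - vy[a]) / (vy[b] - vy[a]) + vx[a])
        wn <- !wn
    }
    inside[i, j] <- wn
  }
  expect_gt(sum(inside & lab == 1L) / sum(lab == 1L), 0.95)
})

test_that("candidate extraction counts and orders suprathreshold pixels", {
  set.seed(31)
  prob <- matrix(runif(30 * 30), 30)
  radii <- array(runif(30 * 30 * 8, 1, 4), c(30, 30, 8))
  cand <- extract_candidates(prob, radii, 0.9)
  expect_equal(nrow(cand), sum(prob >= 0.9))
  expect_true(all(diff(cand$prob) <= 0))
  # all below threshold -> empty; exactly one above -> one candidate
  expect_equal(nrow(extract_candidates(prob * 0 + 0.1, radii, 0.5)), 0)
  p1 <- prob * 0 + 0.1; p1[7, 9] <- 0.95
  c1 <- extract_candidates(p1, radii, 0.5)
  expect_equal(c(c1$row, c1$col), c(7, 9))
  # radii rows track their source pixel
  expect_equal(attr(c1, "radii")[1, ], radii[7, 9, ])
})

test_that("polygon IoU matches a supersampled rasterization oracle", {
  expect_equal(polygon_iou(c(5, 5), rep(2, 32), c(5, 5), rep(2, 32)), 1)
  expect_equal(polygon_iou(c(5, 5), rep(2, 32), c(50, 50), rep(2, 32)), 0)
  expect_equal(polygon_iou(c(5, 5), rep(0, 32), c(5, 5), rep(2, 32)), 0)
  # two unit-radius 32-gons at center distance 1: compare with a 4x
  # supersampled rasterization
  ang <- star_geometry(32)$angles
  ss <- seq(2, 8, by = 0.25)
  inA <- outer(ss, ss, function(y, x) (y - 5)^2 + (x - 5)^2 <= 1)
  inB <- outer(ss, ss, function(y, x) (y - 6)^2 + (x - 5)^2 <= 1)
  oracle <- sum(inA & inB) / sum(inA | inB)
  got <- polygon_iou(c(5, 5), rep(1, 32), c(6, 5), rep(1, 32), ang)
  expect_lt(abs(got - oracle), 0.02)
  expect_equal(got, polygon_iou(c(6, 5), rep(1, 32), c(5, 5), rep(1, 32),
                                ang))       # symmetry
})

test_that("greedy NMS agrees with the brute-force oracle on random sets", {
  for (seed in 1:8) {
    set.seed(seed + 200)
    n <- 200
    prob <- matrix(runif(20 * 20, 0.3, 1), 20)
    radii <- array(runif(20 * 20 * 8, 0.5, 5), c(20, 20, 8))
    cand <- extract_candidates(prob, radii, 0.55)
    cand <- cand[seq_len(min(n, nrow(cand))), ]
    attr(cand, "radii") <- attr(cand, "radii")[seq_len(nrow(cand)), ,
                                               drop = FALSE]
    kept <- nms(cand, 0.4)
    oracle <- nms_oracle(cand, 0.4)
    expect_equal(nrow(kept), length(oracle))
    expect_equal(kept$row, cand$row[oracle])
    expect_equal(kept$col, cand$col[oracle])
  }
  # single candidate survives; of two identical ones the stronger wins
  p <- matrix(0, 10, 10); p[5, 5] <- 0.9; p[5, 6] <- 0.8
  r <- array(3, c(10, 10, 8))
  kept <- nms(extract_candidates(p, r, 0.5), 0.4)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$prob, 0.9)
})

test_that("raising the probability threshold never adds detections", {
  set.seed(77)
  prob <- matrix(runif(25 * 25), 25)
  radii <- array(runif(25 * 25 * 8, 1, 4), c(25, 25, 8))
  n_prev <- Inf
  for (th in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    n <- nrow(nms(extract_candidates(prob, radii, th), 0.4))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("detections export as a valid GeoJSON feature collection", {
  p <- matrix(0, 10, 10); p[5, 5] <- 0.9; p[8, 2] <- 0.7
  r <- array(3, c(10, 10, 8))
  k <- nms(extract_candidates(p, r, 0.5), 0.4)
  path <- withr::local_tempfile(fileext = ".geojson")
  detections_to_geojson(k, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$type, "FeatureCollection")
  expect_length(j$features, nrow(k))
  f1 <- j$features[[1]]
  expect_equal(f1$geometry$type, "Polygon")
  expect_equal(f1$properties$prob, k$prob[1])
  # closed ring: 8 rays + repeated first vertex
  expect_length(f1$geometry$coordinates[[1]], 9)
})

test_that("detector heads have the contracted output shapes and ranges", {
  det <- build_detector(star_geometry(16), base = 4, seed = 2)
  x <- matrix(runif(32 * 32), 32)
  fw <- pdl1tps:::det_forward(det, x)
  expect_equal(dim(fw$prob), c(32, 32))
  expect_equal(dim(fw$radii), c(32, 32, 16))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # determinism at inference
  fw2 <- pdl1tps:::det_forward(det, x)
  expect_identical(fw$prob, fw2$prob)
})
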