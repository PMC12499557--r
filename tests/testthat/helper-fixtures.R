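# Shared fixtures, built in code. Heavyweight objects are created once per
# test run and memoised in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture_cohort <- function(n = 6, seed = 401) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_cohort(synth_config(n_slides = n,
                                                     seed = seed))
  .fixtures[[key]]
}

# independent R ray-marching oracle for star distances; shares the
# documented unit-step/rounding convention but is coded separately from
# the C++ implementation
star_dist_oracle <- function(lab, angles) {
  H <- nrow(lab); W <- ncol(lab)
  out <- array(0, c(H, W, length(angles)))
  for (r in seq_along(angles)) {
    dr <- sin(angles[r]); dc <- cos(angles[r])
    for (i in seq_len(H)) for (j in seq_len(W)) {
      L <- lab[i, j]
      if (L == 0) next
      t <- 1
      while (t < H + W) {
        ii <- round(i - 1 + t * dr) + 1
        jj <- round(j - 1 + t * dc) + 1
        if (ii < 1 || ii > H || jj < 1 || jj > W || lab[ii, jj] != L) break
        t <- t + 1
      }
      out[i, j, r] <- t
    }
  }
  out
}

# brute-force O(n^2) greedy NMS oracle
nms_oracle <- function(cand, iou_thresh) {
  rm <- attr(cand, "radii"); ang <- attr(cand, "angles")
  acc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in acc) {
      if (polygon_iou(c(cand$row[i], cand$col[i]), rm[i, ],
                      c(cand$row[j], cand$col[j]), rm[j, ], ang) >
          iou_thresh) { ok <- FALSE; break }
    }
    if (ok) acc <- c(acc, i)
  }
  acc
}

# random blob instance mask: dilated random seeds, relabeled
random_blob_mask <- function(H = 40, W = 40, n_obj = 4, seed = 1) {
  set.seed(seed)
  lab <- matrix(0L, H, W)
  k <- 0L
  for (o in seq_len(n_obj)) {
    cy <- sample(5:(H - 5), 1); cx <- sample(5:(W - 5), 1)
    r <- sample(2:5, 1)
    rr <- pmax(1, cy - r):pmin(H, cy + r)
    cc <- pmax(1, cx - r):pmin(W, cx + r)
    sel <- outer((rr - cy)^2, (cc - cx)^2, "+") <= r^2
    blk <- lab[rr, cc]
    if (any(blk[sel] > 0)) next   # keep objects disjoint
    k <- k + 1L
    blk[sel] <- k
    lab[rr, cc] <- blk
  }
  lab
}
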