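#' Star-convex ray geometry
#'
#' `n_rays` directions at angles `2*pi*k/n_rays`, `k = 0..n_rays-1`,
#' measured from the +col axis with the row axis pointing down; a polygon
#' vertex along ray `i` is `center + r_i * (sin(theta_i), cos(theta_i))`
#' in `(row, col)` coordinates.
#'
#' @param n_rays number of radial directions (default 32).
#' @return list of class `star_geometry` with `n_rays` and `angles`.
#' @export
star_geometry <- function(n_rays = 32) {
  stopifnot(n_rays >= 3)
  structure(list(n_rays = as.integer(n_rays),
                 angles = 2 * pi * (seq_len(n_rays) - 1) / n_rays),
            class = "star_geometry")
}

#' Radial distance regression targets
#'
#' For every foreground pixel of a labeled instance mask and every ray,
#' the distance (in unit pixel steps) to the first pixel outside the
#' pixel's own object. Marching takes unit steps along the ray and rounds
#' the sampled point to the nearest integer pixel; the recorded distance
#' is the first step index that leaves the object (so an isolated
#' single-pixel object has distance 1 on every ray). Background pixels
#' get 0 on all rays.
#'
#' @param instance_mask integer matrix, 0 = background, positive labels =
#'   objects.
#' @param geom a [star_geometry()].
#' @return array (H, W, n_rays) of distances.
#' @export
star_distance_targets <- function(instance_mask, geom = star_geometry()) {
  stopifnot(is.matrix(instance_mask), min(instance_mask) >= 0)
  m <- matrix(as.integer(instance_mask), nrow(instance_mask))
  cpp_star_dist(m, geom$angles,
                max_steps = max(dim(m)) + 2L)
}

#' Object probability targets
#'
#' Per-object normalized Euclidean distance transform: each foreground
#' pixel's distance to the nearest background pixel, divided by the
#' maximum of that distance within its own object, so every object attains
#' probability 1 at its innermost pixel(s). Background is 0.
#'
#' @inheritParams star_distance_targets
#' @return numeric matrix (H x W) in `[0, 1]`.
#' @export
object_probability_targets <- function(instance_mask) {
  stopifnot(is.matrix(instance_mask), min(instance_mask) >= 0)
  fg <- instance_mask > 0
  if (!any(fg)) return(matrix(0, nrow(instance_mask), ncol(instance_mask)))
  edt <- as.matrix(EBImage::distmap(EBImage::Image(fg * 1)))
  out <- matrix(0, nrow(instance_mask), ncol(instance_mask))
  for (lb in setdiff(unique(as.vector(instance_mask)), 0L)) {
    sel <- instance_mask == lb
    mx <- max(edt[sel])
    out[sel] <- if (mx > 0) edt[sel] / mx else 1
  }
  out
}

#' Build the star-convex nucleus detector
#'
#' A small UNet on the single-channel preprocessed hematoxylin image, with
#' an additional 3x3 feature convolution before the two output heads: a
#' sigmoid-activated 1x1 convolution for the object probability map, and a
#' linear 1x1 convolution for the `n_rays` radial distances.
#'
#' @param geom a [star_geometry()].
#' @param base base channel width (default 8).
#' @param seed weight-initialisation seed.
#' @return model object of class `star_detector`.
#' @export
build_detector <- function(geom = star_geometry(), base = 8, seed = 1L) {
  params <- with_seed(seed, {
    tr <- unet_init(1, base)
    # widened feature conv before the output heads: the radii head must
    # represent n_rays directional distance maps, so it needs more
    # feature channels than the trunk width
    tr$head <- nn_conv_init(base, 4 * base, 3)
    tr$phead <- nn_conv_init(4 * base, 1, 1)
    tr$rhead <- nn_conv_init(4 * base, geom$n_rays, 1)
    tr
  })
  structure(list(geom = geom, base = base, params = params),
            class = "star_detector")
}

det_forward <- function(det, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  x <- x - 0.5   # center [0,1] inputs
  tr <- unet_trunk_fwd(det$params, x)
  pc <- conv_fwd(det$params$phead, tr$feat)
  rc <- conv_fwd(det$params$rhead, tr$feat)
  list(prob = sigmoid(pc$y[, , 1]), plogit = pc$y[, , 1], radii = rc$y,
       cache = list(trunk = tr, pc = pc, rc = rc))
}

det_backward <- function(det, cache, dplogit, dradii) {
  gp <- conv_bwd(det$params$phead, cache$pc,
                 array(dplogit, c(dim(dplogit), 1)))
  gr <- conv_bwd(det$params$rhead, cache$rc, dradii)
  tb <- unet_trunk_bwd(det$params, cache$trunk, gp$dx + gr$dx)
  g <- tb$grads
  g$phead <- gp$grads
  g$rhead <- gr$grads
  g
}

#' Train the nucleus detector on labeled instance masks
#'
#' StarDist-style recipe: binary cross-entropy on the object probability
#' map plus L1 on the radial distances, the latter weighted by the true
#' object probability so that distances only matter inside objects and
#' most near object centers. Trains on random square crops of the
#' supplied images.
#'
#' @param det a [build_detector()] model.
#' @param images list of single-channel preprocessed images (matrices in
#'   `[0, 1]`, e.g. from [nuclei_preprocess()]).
#' @param instance_masks list of matching labeled instance masks.
#' @param hyper list: `lr` (1e-4), `epochs` (10), `crop` (64),
#'   `crops_per_image` (4), `radii_weight` (0.2), `seed` (1).
#' @return list with `model` and `history`.
#' @export
train_detector <- function(det, images, instance_masks, hyper = list()) {
  lr <- hyper$lr %||% 1e-4
  epochs <- hyper$epochs %||% 10
  crop <- hyper$crop %||% 64
  cpi <- hyper$crops_per_image %||% 4
  rw <- hyper$radii_weight %||% 0.2
  seed <- hyper$seed %||% 1L
  stopifnot(length(images) == length(instance_masks), length(images) > 0)
  with_seed(seed, {
    st <- adam_init(det$params)
    history <- data.frame(epoch = integer(0), loss = numeric(0))
    for (ep in seq_len(epochs)) {
      tot <- 0; n <- 0
      for (ii in sample(seq_along(images))) {
        img <- images[[ii]]
        msk <- instance_masks[[ii]]
        H <- nrow(img); W <- ncol(img)
        for (k in seq_len(cpi)) {
          r0 <- sample.int(max(1, H - crop + 1), 1)
          c0 <- sample.int(max(1, W - crop + 1), 1)
          xi <- img[r0:(r0 + crop - 1), c0:(c0 + crop - 1)]
          mi <- msk[r0:(r0 + crop - 1), c0:(c0 + crop - 1)]
          pt <- object_probability_targets(mi)
          dt <- star_distance_targets(mi, det$geom)
          fw <- det_forward(det, xi)
          bl <- bce_loss(fw$prob, pt)
          # d plogit = dprob * sigmoid'
          dpl <- bl$dprob * fw$prob * (1 - fw$prob)
          wr <- array(pt, dim(dt))
          resid <- fw$radii - dt
          rl <- sum(wr * abs(resid)) / length(resid)
          drad <- rw * wr * sign(resid) / length(resid)
          g <- det_backward(det, fw$cache, dpl, drad)
          up <- adam_step(det$params, g, st, lr = lr)
          det$params <- up$params
          st <- up$state
          tot <- tot + bl$loss + rw * rl
          n <- n + 1
        }
      }
      history <- rbind(history, data.frame(epoch = ep, loss = tot / n))
    }
    list(model = det, history = history)
  })
}

#' Extract star-convex candidates from probability and radii maps
#'
#' One candidate per pixel with probability at or above `prob_thresh`,
#' carrying that pixel's radial distances; sorted by probability
#' descending with ties broken by `(row, col)` ascending so downstream
#' suppression is fully deterministic.
#'
#' @param prob matrix (H x W) of object probabilities.
#' @param radii array (H, W, n_rays) of radial distances.
#' @param prob_thresh threshold in (0, 1), default 0.5.
#' @return data.frame of class `star_candidates`: `row`, `col` (1-based
#'   pixel coordinates), `prob`, with the (n x n_rays) radii matrix as
#'   attribute `"radii"` and the geometry angles as attribute `"angles"`.
#' @export
extract_candidates <- function(prob, radii, prob_thresh = 0.5) {
  stopifnot(prob_thresh > 0, prob_thresh < 1)
  sel <- which(prob >= prob_thresh)
  n_rays <- dim(radii)[3]
  if (!length(sel)) {
    out <- data.frame(row = integer(0), col = integer(0), prob = numeric(0))
    attr(out, "radii") <- matrix(0, 0, n_rays)
    attr(out, "angles") <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
    class(out) <- c("star_candidates", class(out))
    return(out)
  }
  H <- nrow(prob)
  rr <- (sel - 1L) %% H + 1L
  cc <- (sel - 1L) %/% H + 1L
  ord <- order(-prob[sel], rr, cc)
  rm <- matrix(radii, ncol = n_rays)[sel, , drop = FALSE]
  out <- data.frame(row = rr[ord], col = cc[ord], prob = prob[sel][ord])
  attr(out, "radii") <- rm[ord, , drop = FALSE]
  attr(out, "angles") <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  class(out) <- c("star_candidates", class(out))
  out
}

#' Intersection-over-union of two star-convex polygons
#'
#' Both polygons are rasterized on the integer lattice covering their
#' joint bounding box and the IoU of the two pixel sets is returned.
#' Symmetric, in `[0, 1]`; a zero-area polygon gives 0 by convention.
#'
#' @param center1,center2 `(row, col)` centers.
#' @param radii1,radii2 radial distance vectors (equal length).
#' @param angles ray angles (default the [star_geometry()] of
#'   `length(radii1)` rays).
#' @return scalar IoU.
#' @export
polygon_iou <- function(center1, radii1, center2, radii2,
                        angles = star_geometry(length(radii1))$angles) {
  stopifnot(length(radii1) == length(radii2),
            all(is.finite(radii1)), all(is.finite(radii2)))
  cpp_poly_iou(as.numeric(center1), as.numeric(radii1),
               as.numeric(center2), as.numeric(radii2), angles)
}

#' Greedy non-maximum suppression of star-convex candidates
#'
#' Accepts the highest-probability candidate, suppresses every remaining
#' candidate whose polygon IoU with any accepted one exceeds
#' `iou_thresh`, and repeats. Deterministic given the candidate ordering
#' produced by [extract_candidates()].
#'
#' @param candidates a [extract_candidates()] result.
#' @param iou_thresh suppression threshold in (0, 1), default 0.4.
#' @return the kept subset, same structure as `candidates`.
#' @export
nms <- function(candidates, iou_thresh = 0.4) {
  stopifnot(iou_thresh > 0, iou_thresh < 1)
  if (nrow(candidates) == 0) return(candidates)
  rm <- attr(candidates, "radii")
  keep <- cpp_nms(cbind(candidates$row, candidates$col), rm,
                  attr(candidates, "angles"), iou_thresh)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "radii") <- rm[keep, , drop = FALSE]
  attr(out, "angles") <- attr(candidates, "angles")
  class(out) <- c("star_candidates", "data.frame")
  out
}

#' Detect nuclei in an RGB patch
#'
#' The full stage-3 chain: hematoxylin isolation and blur
#' ([nuclei_preprocess()]), the trained detector's probability and radii
#' maps, candidate extraction, and greedy NMS. Centroids are reported in
#' native patch coordinates.
#'
#' @param det a trained [build_detector()] model.
#' @param image RGB patch (H, W, 3), values 0-255; H and W must be
#'   divisible by 4 (the detector's UNet stride).
#' @param M stain matrix for the deconvolution.
#' @param blur_sigma preprocessing blur, default 1.
#' @param prob_thresh,iou_thresh detection thresholds (defaults 0.5, 0.4).
#' @return a `star_candidates` data.frame of kept detections.
#' @export
detect_nuclei <- function(det, image, M = stain_matrix_hdab(),
                          blur_sigma = 1.0, prob_thresh = 0.5,
                          iou_thresh = 0.4) {
  if (is.null(det$params))
    stop("detector has no weights; train with train_detector() or load a ",
         "checkpoint")
  x <- nuclei_preprocess(image, M, blur_sigma)
  fw <- det_forward(det, x)
  nms(extract_candidates(fw$prob, fw$radii, prob_thresh), iou_thresh)
}

#' Export detections as GeoJSON
#'
#' Writes each kept detection as a GeoJSON Feature with its polygon
#' (closed ring, `(x, y) = (col, row)` order), centroid and probability.
#'
#' @param detections a `star_candidates` data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
detections_to_geojson <- function(detections, path) {
  ang <- attr(detections, "angles")
  rm <- attr(detections, "radii")
  feats <- lapply(seq_len(nrow(detections)), function(i) {
    vx <- detections$col[i] + rm[i, ] * cos(ang)
    vy <- detections$row[i] + rm[i, ] * sin(ang)
    ring <- cbind(c(vx, vx[1]), c(vy, vy[1]))
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))),
         properties = list(prob = detections$prob[i],
                           centroid = c(detections$col[i],
                                        detections$row[i]),
                           status = if ("status" %in% names(detections))
                             detections$status[i] else NULL))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
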