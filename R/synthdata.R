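#' Configuration for the synthetic H-DAB slide generator
#'
#' The generator emulates the statistical structure of a DAB-stained NSCLC
#' cohort at desk scale: hematoxylin-dark elliptical nuclei packed into
#' tumor blobs, a brown membranous DAB ring around the PD-L1-positive
#' subset, a three-class region mask (0 non-tumor, 1 positive tumor,
#' 2 negative tumor), artifact smears in non-tissue tiles, and an exact
#' per-slide tumor proportion score. Slides are assigned to the three
#' clinical TPS strata (<1%, 1-49%, >=50%) with the cohort fractions
#' 45.5% / 33.3% / 21.2%.
#'
#' @param n_slides number of slides in the cohort.
#' @param slide_size integer `(H, W)` in pixels.
#' @param cells_per_slide integer range `(min, max)` of viable tumor cells.
#' @param nucleus_radius pixel range of ellipse semi-axes.
#' @param true_tps_strata list of `list(frac=, tps=c(lo, hi))` covering the
#'   three strata; fractions must sum to 1. TPS is drawn uniformly from
#'   `tps`; the default interior ranges (0, 5-45, 55-95) keep every
#'   realized slide inside its stratum.
#' @param stain_intensity list with OD peak ranges `hematoxylin` and `dab`.
#' @param noise_sd per-channel additive Gaussian noise, uint8 units.
#' @param artifact_rate fraction of non-tissue tiles given artifact smears.
#' @param intensity_var multiplier widening per-cell stain draws
#'   (staining heterogeneity knob).
#' @param patch_size tile size used to decide how many artifact smears a
#'   slide receives (`artifact_rate` is per tile).
#' @param bg_nuclei_frac non-tumor (excluded) nuclei as a fraction of tumor
#'   cells, scattered outside tumor regions.
#' @param seed RNG seed for the whole cohort; slide `i` derives its own
#'   stream from `(seed, i)`.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_slides = 30,
                         slide_size = c(512, 512),
                         cells_per_slide = c(150, 220),
                         nucleus_radius = c(3, 5),
                         true_tps_strata = list(
                           list(frac = 0.455, tps = c(0, 0)),
                           list(frac = 0.333, tps = c(5, 45)),
                           list(frac = 0.212, tps = c(55, 95))),
                         stain_intensity = list(hematoxylin = c(0.55, 0.85),
                                                dab = c(0.45, 0.75)),
                         noise_sd = 2.0,
                         artifact_rate = 0.15,
                         intensity_var = 1.0,
                         patch_size = 128,
                         bg_nuclei_frac = 0.08,
                         seed = 1L) {
  cfg <- list(n_slides = n_slides, slide_size = as.integer(slide_size),
              cells_per_slide = as.integer(cells_per_slide),
              nucleus_radius = nucleus_radius,
              true_tps_strata = true_tps_strata,
              stain_intensity = stain_intensity, noise_sd = noise_sd,
              artifact_rate = artifact_rate, intensity_var = intensity_var,
              patch_size = as.integer(patch_size),
              bg_nuclei_frac = bg_nuclei_frac, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fr <- vapply(cfg$true_tps_strata, function(s) s$frac, numeric(1))
  if (abs(sum(fr) - 1) > 1e-6)
    stop("true_tps_strata fractions must sum to 1 (got ", sum(fr), ")")
  if (any(cfg$nucleus_radius <= 0)) stop("nucleus_radius must be positive")
  if (cfg$cells_per_slide[1] > cfg$cells_per_slide[2])
    stop("cells_per_slide range reversed")
  if (cfg$noise_sd < 0 || cfg$artifact_rate < 0 || cfg$artifact_rate > 1)
    stop("noise_sd must be >= 0 and artifact_rate in [0, 1]")
  invisible(cfg)
}

# Linear pixel indices inside a rotated ellipse, restricted to the image.
ellipse_pixels <- function(H, W, cy, cx, a, b, phi, scale = 1) {
  ra <- a * scale
  rb <- b * scale
  ext <- ceiling(max(ra, rb)) + 1L
  rows <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
  cols <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  u <- (rr - cy) * cos(phi) + (cc - cx) * sin(phi)
  v <- -(rr - cy) * sin(phi) + (cc - cx) * cos(phi)
  inside <- (u / ra)^2 + (v / rb)^2 <= 1
  (cc[inside] - 1L) * H + rr[inside]
}

# Dart-throwing with a minimum center separation over candidate pixels.
throw_darts <- function(candidates_rc, n, min_sep, max_tries) {
  acc <- matrix(0, 0, 2)
  tries <- 0L
  i <- 1L
  ord <- sample.int(nrow(candidates_rc))
  while (nrow(acc) < n && tries < max_tries && i <= length(ord)) {
    p <- candidates_rc[ord[i], ]
    i <- i + 1L
    tries <- tries + 1L
    if (nrow(acc) == 0 ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= min_sep^2)
      acc <- rbind(acc, p)
  }
  acc
}

#' Render an RGB image from stain concentration fields
#'
#' Beer-Lambert forward model: per-pixel optical density
#' `OD = c_h * H_vec + c_dab * DAB_vec`, intensity
#' `I = (I0 + eps) * 10^(-OD) - eps` with `I0 = 255`, the exact inverse of
#' [rgb_to_od()]. Zero concentration renders pure white (255).
#'
#' @param h_conc,dab_conc numeric matrices (H x W) of nonnegative stain
#'   concentrations (1.0 = one unit of the stain vector's OD).
#' @param M stain matrix (rows hematoxylin, DAB, residual).
#' @param eps log-guard offset matching [rgb_to_od()].
#' @return numeric RGB array (H, W, 3) in `[0, 255]` (continuous scale;
#'   quantization to uint8 is left to the caller).
#' @export
forward_stain_render <- function(h_conc, dab_conc, M = stain_matrix_hdab(),
                                 eps = 1) {
  stopifnot(all(dim(h_conc) == dim(dab_conc)))
  if (min(h_conc) < 0 || min(dab_conc) < 0)
    stop("stain concentrations must be nonnegative")
  d <- dim(h_conc)
  od <- outer(c(h_conc), M[1, ]) + outer(c(dab_conc), M[2, ])
  img <- clamp((255 + eps) * 10^(-od) - eps, 0, 255)
  array(img, c(d[1], d[2], 3))
}

#' Generate one synthetic slide with exact ground truth
#'
#' Deterministic given `(cfg$seed, slide_index)`. Tumor tissue is laid out
#' as elliptical blobs; nuclei are non-overlapping ellipses placed by
#' dart-throwing with a minimum separation; the PD-L1-positive subset
#' (count chosen to realize the slide's target TPS exactly) is clustered
#' around random expression foci and rendered with a DAB-brown membranous
#' annulus. The region mask labels every tumor-blob pixel with the status
#' of its nearest cell (1 positive, 2 negative); everything else is class
#' 0. A fraction of non-tissue tiles receives saturated artifact smears
#' and a few excluded non-tumor nuclei are scattered in the background.
#'
#' @param cfg a [synth_config()].
#' @param slide_index slide number in `1:cfg$n_slides`.
#' @return list of class `synth_slide` with fields `image` (uint8-valued
#'   RGB array), `region_mask` (H x W integer, 0/1/2), `instance_mask`
#'   (H x W integer nucleus labels), `centroids` (data.frame row, col,
#'   status), `true_tps` (percent), `stratum`, `slide_id`.
#' @export
generate_slide <- function(cfg, slide_index) {
  validate_synth_config(cfg)
  stopifnot(slide_index >= 1, slide_index <= cfg$n_slides)
  with_seed(mix_seed(cfg$seed, slide_index), {
    H <- cfg$slide_size[1]; W <- cfg$slide_size[2]
    fr <- vapply(cfg$true_tps_strata, `[[`, numeric(1), "frac")
    stratum <- sample.int(length(fr), 1, prob = fr)
    tr <- cfg$true_tps_strata[[stratum]]$tps
    target_tps <- if (tr[1] == tr[2]) tr[1] else runif(1, tr[1], tr[2])

    # tumor blobs
    # tumor blobs live in a random sub-window so slides also contain
    # tissue-free tiles; blobs accumulate until the window is ~45%
    # covered, enough area to pack the cells at the minimum separation
    win <- round(0.72 * min(H, W))
    w0r <- sample.int(H - win + 1, 1)
    w0c <- sample.int(W - win + 1, 1)
    tumor <- matrix(FALSE, H, W)
    for (k in seq_len(16)) {
      if (k > 4 && sum(tumor) >= 0.45 * win * win) break
      idx <- ellipse_pixels(H, W, w0r + runif(1, 0.15, 0.85) * win,
                            w0c + runif(1, 0.15, 0.85) * win,
                            runif(1, 0.12, 0.22) * win,
                            runif(1, 0.10, 0.18) * win,
                            runif(1, 0, pi))
      tumor[idx] <- TRUE
    }

    # nuclei by dart-throwing
    rmax <- max(cfg$nucleus_radius)
    min_sep <- 2 * rmax + 3
    n_cells <- sample(cfg$cells_per_slide[1]:cfg$cells_per_slide[2], 1)
    tpix <- which(tumor)
    cand <- cbind((tpix - 1L) %% H + 1L, (tpix - 1L) %/% H + 1L)
    cells <- throw_darts(cand, n_cells, min_sep, 400L * n_cells)
    if (nrow(cells) < n_cells)
      stop("cells_per_slide (", n_cells, ") exceeds the packable tumor ",
           "area at minimum separation ", min_sep, " px; got ",
           nrow(cells), " placements")

    # positivity: cluster around expression foci to mimic heterogeneity
    n_pos <- round(target_tps / 100 * n_cells)
    status <- rep("negative", n_cells)
    if (n_pos > 0) {
      n_foci <- sample(1:2, 1)
      foci <- cand[sample.int(nrow(cand), n_foci), , drop = FALSE]
      sc <- apply(foci, 1, function(f)
        sqrt((cells[, 1] - f[1])^2 + (cells[, 2] - f[2])^2))
      sc <- if (is.matrix(sc)) apply(sc, 1, min) else sc
      status[order(sc)[seq_len(n_pos)]] <- "positive"
    }
    true_tps <- 100 * n_pos / n_cells

    # region mask: nearest-cell status over tumor pixels (chunked)
    region <- matrix(0L, H, W)
    lab <- ifelse(status == "positive", 1L, 2L)
    for (st in seq(1, length(tpix), by = 20000L)) {
      en <- min(st + 19999L, length(tpix))
      pr <- cand[st:en, 1]; pc <- cand[st:en, 2]
      d2 <- outer(pr, cells[, 1], "-")^2 + outer(pc, cells[, 2], "-")^2
      region[tpix[st:en]] <- lab[max.col(-d2, ties.method = "first")]
    }

    # render nuclei and membranous DAB rings
    iv <- cfg$intensity_var
    hr <- cfg$stain_intensity$hematoxylin
    dr <- cfg$stain_intensity$dab
    h_conc <- matrix(0, H, W)
    h_conc[tumor] <- 0.06             # faint tissue haze
    dab_conc <- matrix(0, H, W)
    inst <- matrix(0L, H, W)
    geom <- matrix(0, n_cells, 3)     # a, b, phi
    for (i in seq_len(n_cells)) {
      a <- runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
      b <- runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
      phi <- runif(1, 0, pi)
      geom[i, ] <- c(a, b, phi)
      idx <- ellipse_pixels(H, W, cells[i, 1], cells[i, 2], a, b, phi)
      inst[idx] <- i
      h_conc[idx] <- pmax(h_conc[idx],
                          runif(1, hr[1], hr[2]) *
                            (1 + iv * runif(1, -0.1, 0.1)))
      if (status[i] == "positive") {
        ring <- setdiff(ellipse_pixels(H, W, cells[i, 1], cells[i, 2],
                                       a, b, phi, scale = 1.45),
                        ellipse_pixels(H, W, cells[i, 1], cells[i, 2],
                                       a, b, phi, scale = 1.05))
        dab_conc[ring] <- pmax(dab_conc[ring],
                               runif(1, dr[1], dr[2]) *
                                 (1 + iv * runif(1, -0.15, 0.15)))
      }
    }

    # excluded non-tumor nuclei in the background
    n_bg <- round(cfg$bg_nuclei_frac * n_cells)
    bg_cells <- matrix(0, 0, 2)
    if (n_bg > 0) {
      bpix <- which(!tumor)
      bcand <- cbind((bpix - 1L) %% H + 1L, (bpix - 1L) %/% H + 1L)
      # keep background nuclei clear of tumor blobs and of each other
      bg_cells <- throw_darts(bcand, n_bg, min_sep, 100L * n_bg)
      for (i in seq_len(nrow(bg_cells))) {
        a <- runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
        b <- runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
        phi <- runif(1, 0, pi)
        idx <- ellipse_pixels(H, W, bg_cells[i, 1], bg_cells[i, 2], a, b, phi)
        idx <- idx[region[idx] == 0L]
        inst[idx] <- n_cells + i
        h_conc[idx] <- pmax(h_conc[idx], runif(1, hr[1], hr[2]))
      }
    }

    img <- forward_stain_render(h_conc, dab_conc)

    # artifact smears on non-tissue tiles
    ps <- cfg$patch_size
    n_tiles <- floor(H / ps) * floor(W / ps)
    n_art <- rbinom(1, n_tiles, cfg$artifact_rate)
    for (k in seq_len(n_art)) {
      cy <- runif(1, 1, H); cx <- runif(1, 1, W)
      tries <- 0
      while (tumor[round(clamp(cy, 1, H)), round(clamp(cx, 1, W))] &&
             tries < 50) {
        cy <- runif(1, 1, H); cx <- runif(1, 1, W); tries <- tries + 1
      }
      rad <- runif(1, 0.05, 0.12) * min(H, W)
      rr <- matrix(seq_len(H), H, W)
      cc <- matrix(seq_len(W), H, W, byrow = TRUE)
      alpha <- exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * rad^2)) *
        runif(1, 0.7, 1)
      alpha[tumor | inst > 0L] <- 0   # artifacts live on non-tissue only
      col <- if (runif(1) < 0.5) c(60, 60, 60) else c(160, 120, 60)
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - alpha) + col[ch] * alpha
    }

    img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img))
    img <- round(clamp(img, 0, 255))

    centroids <- data.frame(
      row = c(cells[, 1], bg_cells[, 1]),
      col = c(cells[, 2], bg_cells[, 2]),
      status = c(status, rep("non-tumor", nrow(bg_cells))),
      stringsAsFactors = FALSE)

    structure(list(image = img, region_mask = region, instance_mask = inst,
                   centroids = centroids, true_tps = true_tps,
                   stratum = stratum,
                   slide_id = sprintf("slide_%03d", slide_index)),
              class = "synth_slide")
  })
}

#' Generate a cohort of synthetic slides
#' @param cfg a [synth_config()].
#' @param indices which slides to generate (default all).
#' @return list of [generate_slide()] results.
#' @export
generate_cohort <- function(cfg, indices = seq_len(cfg$n_slides)) {
  lapply(indices, function(i) generate_slide(cfg, i))
}

#' @export
print.synth_slide <- function(x, ...) {
  cat(sprintf("<synth_slide %s> %dx%d px, %d nuclei (%d positive), TPS %.2f%%\n",
              x$slide_id, nrow(x$image), ncol(x$image),
              nrow(x$centroids),
              sum(x$centroids$status == "positive"), x$true_tps))
  invisible(x)
}

#' Write a synthetic slide to disk
#'
#' Image as TIFF, region mask as single-channel PNG (pixel values 0/1/2),
#' centroids as CSV, true TPS as JSON.
#'
#' @param slide a `synth_slide`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, slide$slide_id)
  tiff::writeTIFF(slide$image / 255, paste0(base, ".tiff"))
  png::writePNG(slide$region_mask / 255, paste0(base, "_mask.png"))
  cen <- cbind(slide_id = slide$slide_id, slide$centroids)
  write.csv(cen, paste0(base, "_centroids.csv"), row.names = FALSE)
  jsonlite::write_json(list(slide_id = slide$slide_id,
                            true_tps = slide$true_tps),
                       paste0(base, "_tps.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, c(".tiff", "_mask.png", "_centroids.csv",
                           "_tps.json")))
}

#' Read a slide image and optional mask written by [write_slide()]
#' @param image_path TIFF/PNG image path.
#' @param mask_path optional single-channel PNG mask (values 0/1/2).
#' @return list with `image` (H, W, 3 array, 0-255) and `region_mask`
#'   (integer matrix or NULL).
#' @export
read_slide_image <- function(image_path, mask_path = NULL) {
  img <- if (grepl("\\.tiff?$", image_path, ignore.case = TRUE))
    tiff::readTIFF(image_path) else png::readPNG(image_path)
  img <- round(img * 255)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    mask <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  }
  list(image = img, region_mask = mask)
}
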