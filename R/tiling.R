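#' Tile a slide image into fixed-size patches
#'
#' Cuts a slide into a regular, row-major grid of `patch_size` tiles
#' (stride defaults to `patch_size`, i.e. non-overlapping). Coordinates are
#' 0-based `(row, col)` with half-open tile extents
#' `[origin, origin + patch_size)`. Partial edge tiles are dropped. When a
#' label mask is supplied each tile is labeled `"tumor"` iff it contains at
#' least `min_tumor_pixels` pixels of class 1 or 2 — the any-tumor-cell
#' labeling rule — and carries its mask crop.
#'
#' @param image RGB array (H, W, 3) or matrix.
#' @param mask optional integer matrix (H x W) with values 0/1/2.
#' @param patch_size tile side in pixels (default 1000, the native
#'   full-scale setting; scale down for small synthetic slides).
#' @param stride grid step, default `patch_size`.
#' @param min_tumor_pixels tumor-pixel count threshold for the tumor label.
#' @param slide_id identifier stored in each record.
#' @return data.frame of patch records (one row per tile): `slide_id`,
#'   `grid_row`, `grid_col`, `origin_row`, `origin_col`, `cls_label`, plus
#'   list-columns `image` and `mask` holding the crops. Zero rows (with a
#'   warning) when the image is smaller than `patch_size`.
#' @export
tile_slide <- function(image, mask = NULL, patch_size = 1000,
                       stride = patch_size, min_tumor_pixels = 1,
                       slide_id = "slide") {
  stopifnot(patch_size > 0, stride > 0)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (!is.null(mask))
    stopifnot(nrow(mask) == H, ncol(mask) == W)
  n_r <- if (H >= patch_size) floor((H - patch_size) / stride) + 1 else 0
  n_c <- if (W >= patch_size) floor((W - patch_size) / stride) + 1 else 0
  if (n_r == 0 || n_c == 0) {
    warning("image (", H, "x", W, ") smaller than patch_size ", patch_size,
            "; no tiles produced")
    return(empty_patch_records())
  }
  rows <- list()
  for (gr in 0:(n_r - 1)) {
    for (gc in 0:(n_c - 1)) {
      or <- gr * stride; oc <- gc * stride
      ri <- (or + 1):(or + patch_size)
      ci <- (oc + 1):(oc + patch_size)
      pm <- if (is.null(mask)) NULL else mask[ri, ci, drop = FALSE]
      lab <- if (is.null(pm)) NA_character_ else
        if (sum(pm > 0) >= min_tumor_pixels) "tumor" else "non-tumor"
      pimg <- if (length(d) == 3) image[ri, ci, , drop = FALSE]
              else image[ri, ci, drop = FALSE]
      rows[[length(rows) + 1]] <- list(
        slide_id = slide_id, grid_row = gr, grid_col = gc,
        origin_row = or, origin_col = oc, cls_label = lab,
        image = pimg, mask = pm)
    }
  }
  out <- data.frame(
    slide_id = vapply(rows, `[[`, character(1), "slide_id"),
    grid_row = vapply(rows, `[[`, numeric(1), "grid_row"),
    grid_col = vapply(rows, `[[`, numeric(1), "grid_col"),
    origin_row = vapply(rows, `[[`, numeric(1), "origin_row"),
    origin_col = vapply(rows, `[[`, numeric(1), "origin_col"),
    cls_label = vapply(rows, `[[`, character(1), "cls_label"),
    stringsAsFactors = FALSE)
  out$image <- lapply(rows, `[[`, "image")
  out$mask <- lapply(rows, `[[`, "mask")
  out
}

empty_patch_records <- function() {
  out <- data.frame(slide_id = character(0), grid_row = numeric(0),
                    grid_col = numeric(0), origin_row = numeric(0),
                    origin_col = numeric(0), cls_label = character(0),
                    stringsAsFactors = FALSE)
  out$image <- list()
  out$mask <- list()
  out
}

#' Assign slides to cross-validation folds
#'
#' Slide-level (patient-wise) folds: every slide lands in exactly one fold,
#' so all patches of a slide share its fold and no slide can leak between
#' train and test. Shuffled round-robin gives near-balanced sizes (max
#' difference 1); deterministic given `seed`. With 66 slides and 5 folds
#' the sizes are 14, 13, 13, 13, 13.
#'
#' @param slide_ids character vector of unique slide identifiers.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed.
#' @return data.frame of class `fold_assignment`: `slide_id`, `fold`
#'   (1-based).
#' @export
assign_folds <- function(slide_ids, n_folds = 5, seed = 1L) {
  if (anyDuplicated(slide_ids))
    stop("duplicate slide_ids: ",
         paste(unique(slide_ids[duplicated(slide_ids)]), collapse = ", "))
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > length(slide_ids))
    stop("n_folds (", n_folds, ") exceeds number of slides (",
         length(slide_ids), ")")
  ord <- with_seed(seed, sample(seq_along(slide_ids)))
  out <- data.frame(slide_id = slide_ids[ord],
                    fold = rep_len(seq_len(n_folds), length(slide_ids)),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$slide_id, slide_ids)), ]
  rownames(out) <- NULL
  class(out) <- c("fold_assignment", class(out))
  out
}

#' Write patch records to disk as PNG files
#'
#' @param records output of [tile_slide()] (rows from several slides may be
#'   concatenated with `rbind`).
#' @param dir output directory.
#' @return `records` with `image_path` / `mask_path` columns added and the
#'   in-memory crops dropped.
#' @export
write_patches <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(records)
  ip <- mp <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    stem <- sprintf("%s_r%d_c%d", records$slide_id[i], records$grid_row[i],
                    records$grid_col[i])
    ip[i] <- file.path(dir, paste0(stem, ".png"))
    png::writePNG(records$image[[i]] / 255, ip[i])
    if (!is.null(records$mask[[i]])) {
      mp[i] <- file.path(dir, paste0(stem, "_mask.png"))
      png::writePNG(records$mask[[i]] / 255, mp[i])
    }
  }
  records$image_path <- ip
  records$mask_path <- mp
  records$image <- NULL
  records$mask <- NULL
  records
}

#' Build classification and segmentation manifests
#'
#' The classification manifest lists every patch with its tumor/non-tumor
#' label; the segmentation manifest lists only tumor-labeled patches (the
#' ones that carry masks). Each row inherits its slide's fold.
#'
#' @param records patch records (from [tile_slide()], optionally after
#'   [write_patches()]).
#' @param folds a [assign_folds()] result covering every slide in
#'   `records`.
#' @return list with data.frames `classification` and `segmentation`.
#' @export
build_manifests <- function(records, folds) {
  meta_cols <- intersect(c("slide_id", "grid_row", "grid_col", "origin_row",
                           "origin_col", "cls_label", "image_path",
                           "mask_path"), names(records))
  if (nrow(records) == 0) {
    cls <- records[meta_cols]
    cls$fold <- integer(0)
    return(list(classification = cls, segmentation = cls))
  }
  missing <- setdiff(unique(records$slide_id), folds$slide_id)
  if (length(missing))
    stop("records reference slides without fold assignment: ",
         paste(missing, collapse = ", "))
  cls <- records[meta_cols]
  cls$fold <- folds$fold[match(records$slide_id, folds$slide_id)]
  if ("image" %in% names(records)) cls$image <- records$image
  if ("mask" %in% names(records)) cls$mask <- records$mask
  seg <- cls[cls$cls_label == "tumor", , drop = FALSE]
  has_mask <- if ("mask" %in% names(seg))
    !vapply(seg$mask, is.null, logical(1))
  else if ("mask_path" %in% names(seg)) !is.na(seg$mask_path)
  else rep(FALSE, nrow(seg))
  if (nrow(seg) > 0 && any(!has_mask))
    stop("tumor-labeled patches without masks: ",
         paste(sprintf("%s r%d c%d", seg$slide_id[!has_mask],
                       seg$grid_row[!has_mask], seg$grid_col[!has_mask]),
               collapse = "; "))
  rownames(seg) <- NULL
  list(classification = cls, segmentation = seg)
}
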