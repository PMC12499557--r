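#' Stain-threshold baseline region segmenter
#'
#' A model-free baseline built directly on color deconvolution: nuclei are
#' the connected components of thresholded hematoxylin concentration, a
#' nucleus is called PD-L1-positive when a DAB-stained pixel lies within
#' `ring_gap` of it (membranous ring), tissue extent is taken from the
#' blurred hematoxylin haze, and every tissue pixel is assigned the class
#' of its nearest nucleus (Voronoi rule): 1 near positive nuclei, 2 near
#' negative nuclei, 0 elsewhere.
#'
#' On rendered H-DAB images the region classes are nearly separable by
#' stain color, so this baseline serves as an independent oracle against
#' which the trained segmentation networks are sanity-checked.
#'
#' @param image RGB patch (H, W, 3), values 0-255.
#' @param M stain matrix.
#' @param dab_thresh,h_thresh DAB / hematoxylin concentration thresholds
#'   for stained pixels.
#' @param haze_thresh threshold on the sigma-2 blurred hematoxylin map
#'   delimiting tissue.
#' @param ring_gap maximum nucleus-to-DAB distance (pixels) for a nucleus
#'   to count as positive.
#' @return integer matrix (H x W) with values 0/1/2.
#' @export
threshold_region_mask <- function(image, M = stain_matrix_hdab(),
                                  dab_thresh = 0.12, h_thresh = 0.3,
                                  haze_thresh = 0.035, ring_gap = 4) {
  conc <- deconvolve(rgb_to_od(image), M)
  H <- nrow(conc$dab); W <- ncol(conc$dab)
  tissue <- as.matrix(EBImage::gblur(conc$hematoxylin, 2)) > haze_thresh
  dabm <- conc$dab > dab_thresh
  hm <- conc$hematoxylin > h_thresh
  dist_to <- function(mask) {
    if (!any(mask)) return(matrix(Inf, H, W))
    as.matrix(EBImage::distmap(EBImage::Image((!mask) * 1)))
  }
  labm <- as.matrix(EBImage::bwlabel(EBImage::Image(hm * 1)))
  dab_d <- dist_to(dabm)
  posm <- negm <- matrix(FALSE, H, W)
  for (L in seq_len(max(labm))) {
    sel <- labm == L
    if (min(dab_d[sel]) <= ring_gap) posm[sel] <- TRUE else negm[sel] <- TRUE
  }
  pos_d <- dist_to(posm)
  neg_d <- dist_to(negm)
  out <- matrix(0L, H, W)
  fin <- is.finite(pmin(pos_d, neg_d))
  out[tissue & fin & (pos_d <= neg_d)] <- 1L
  out[tissue & fin & (neg_d < pos_d)] <- 2L
  out
}

#' Pooled segmentation metrics over many tiles
#'
#' Micro-aggregation: per-class intersections and set sizes are summed
#' over all (true, predicted) mask pairs before the IoU/DSC ratios are
#' formed, so tiny tiles do not dominate the summary.
#'
#' @param true_masks,pred_masks lists of matching 0/1/2 masks.
#' @return list with `per_class` data.frame (`iou`, `dsc` for classes 1
#'   and 2), `overall` (unweighted mean over the two tumor classes), and
#'   `pixel_accuracy`.
#' @export
pooled_segmentation_metrics <- function(true_masks, pred_masks) {
  stopifnot(length(true_masks) == length(pred_masks),
            length(true_masks) > 0)
  inter <- szA <- szB <- c(0, 0)
  correct <- total <- 0
  for (k in seq_along(true_masks)) {
    tm <- true_masks[[k]]; pm <- pred_masks[[k]]
    for (cl in 1:2) {
      A <- tm == cl; B <- pm == cl
      inter[cl] <- inter[cl] + sum(A & B)
      szA[cl] <- szA[cl] + sum(A)
      szB[cl] <- szB[cl] + sum(B)
    }
    correct <- correct + sum(tm == pm)
    total <- total + length(tm)
  }
  dsc <- ifelse(szA + szB == 0, 1, 2 * inter / (szA + szB))
  iou <- ifelse(szA + szB - inter == 0, 1, inter / (szA + szB - inter))
  per_class <- data.frame(class = 1:2, iou = iou, dsc = dsc)
  list(per_class = per_class,
       overall = list(iou = mean(iou), dsc = mean(dsc)),
       pixel_accuracy = correct / total)
}
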