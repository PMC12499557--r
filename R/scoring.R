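#' Assign PD-L1 status to detected nuclei from the region mask
#'
#' A detection whose centroid pixel lies in segmentation class 1 (positive
#' tumor region) is a PD-L1-positive cancer cell; class 2 makes it
#' negative; class 0 (non-tumor) excludes it from the score entirely —
#' immune, normal, necrotic and other non-neoplastic cells never count
#' toward the TPS.
#'
#' @param detections data.frame with `row`, `col` centroids (patch
#'   coordinates, 1-based).
#' @param region_mask integer matrix (H x W) with values 0/1/2 at the same
#'   resolution as the detection coordinates.
#' @return `detections` with a `status` column
#'   (`"positive"`/`"negative"`/`"excluded"`).
#' @export
assign_status <- function(detections, region_mask) {
  if (nrow(detections) == 0) {
    detections$status <- character(0)
    return(detections)
  }
  r <- round(detections$row)
  c <- round(detections$col)
  bad <- r < 1 | r > nrow(region_mask) | c < 1 | c > ncol(region_mask)
  if (any(bad))
    stop("detection centroid out of mask bounds at (row, col) = (",
         r[which(bad)[1]], ", ", c[which(bad)[1]], ")")
  cls <- region_mask[cbind(r, c)]
  detections$status <- c("excluded", "positive", "negative")[cls + 1L]
  detections
}

#' Tumor proportion score from cell counts
#'
#' `TPS = 100 * P / (P + N)` where `P` is the number of PD-L1-positive
#' viable tumor cells and `N` the number of negative ones. When no viable
#' tumor cells are present the score is undefined: `NA` is returned with a
#' `"no viable tumor cells"` flag attribute and a warning, never 0.
#'
#' @param n_positive,n_negative nonnegative cell counts.
#' @return TPS percentage in `[0, 100]`, or flagged `NA`.
#' @export
compute_tps <- function(n_positive, n_negative) {
  stopifnot(n_positive >= 0, n_negative >= 0)
  if (n_positive + n_negative == 0) {
    warning("no viable tumor cells; TPS undefined")
    return(structure(NA_real_, flag = "no viable tumor cells"))
  }
  100 * n_positive / (n_positive + n_negative)
}

#' Clinical three-level PD-L1 expression category
#'
#' `negative` for TPS < 1%, `high` for TPS >= 50%, `low` otherwise
#' (i.e. `[1, 50)`; the clinical 22C3 convention treats everything below
#' 50 but at least 1 as low expression). Vectorized; `NA` in, `NA` out.
#'
#' @param tps TPS percentage(s) in `[0, 100]`.
#' @return factor with levels `negative`, `low`, `high`.
#' @export
categorize_tps <- function(tps) {
  stopifnot(all(is.na(tps) | (tps >= 0 & tps <= 100)))
  out <- ifelse(is.na(tps), NA_character_,
                ifelse(tps < 1, "negative",
                       ifelse(tps >= 50, "high", "low")))
  factor(out, levels = c("negative", "low", "high"))
}

#' Score one slide through the three-stage pipeline
#'
#' Tiles the slide, discards non-tumor patches with the stage-1
#' classifier, predicts the positive/negative region mask with the
#' stage-2 segmentation model, detects nuclei with the stage-3 star-convex
#' detector, assigns each nucleus a status from its centroid pixel, and
#' aggregates the counts into the slide's TPS and clinical category.
#'
#' With `oracle = TRUE` the ground-truth region mask and centroids of a
#' `synth_slide` are injected in place of the three models — the counting
#' identity used to validate the aggregation path.
#'
#' @param slide a `synth_slide`, or a list with `image` (and, for oracle
#'   mode, `region_mask` and `centroids`).
#' @param models list with `cls`, `seg`, `det` models (ignored in oracle
#'   mode).
#' @param patch_size,stride tiling geometry.
#' @param oracle use ground truth instead of models.
#' @param segment_all when TRUE, segment every patch regardless of the
#'   stage-1 call (ablation flag).
#' @param prob_thresh,iou_thresh detector thresholds.
#' @param blur_sigma preprocessing blur for detection.
#' @return list of class `slide_score`: `slide_id`, `n_positive`,
#'   `n_negative`, `n_excluded`, `tps`, `category`, `flag`,
#'   `n_patches_used`.
#' @export
score_slide <- function(slide, models = NULL, patch_size = 128,
                        stride = patch_size, oracle = FALSE,
                        segment_all = FALSE, prob_thresh = 0.5,
                        iou_thresh = 0.4, blur_sigma = 1.0) {
  slide_id <- slide$slide_id %||% "slide"
  tiles <- tile_slide(slide$image,
                      mask = if (oracle) slide$region_mask else NULL,
                      patch_size = patch_size, stride = stride,
                      slide_id = slide_id)
  n_pos <- n_neg <- n_exc <- 0L
  used <- 0L
  for (i in seq_len(nrow(tiles))) {
    or <- tiles$origin_row[i]; oc <- tiles$origin_col[i]
    if (oracle) {
      mask <- tiles$mask[[i]]
      cen <- slide$centroids
      inside <- cen$row > or & cen$row <= or + patch_size &
        cen$col > oc & cen$col <= oc + patch_size
      det <- data.frame(row = cen$row[inside] - or,
                        col = cen$col[inside] - oc)
      if (nrow(det) == 0) next
      used <- used + 1L
    } else {
      pc <- predict_patch_class(models$cls, tiles$image[[i]])
      if (pc$label == "non-tumor" && !segment_all) next
      used <- used + 1L
      mask <- predict_region_mask(models$seg, tiles$image[[i]])
      det <- detect_nuclei(models$det, tiles$image[[i]],
                           blur_sigma = blur_sigma,
                           prob_thresh = prob_thresh,
                           iou_thresh = iou_thresh)
    }
    det <- assign_status(det, mask)
    n_pos <- n_pos + sum(det$status == "positive")
    n_neg <- n_neg + sum(det$status == "negative")
    n_exc <- n_exc + sum(det$status == "excluded")
  }
  flag <- NULL
  tps <- if (n_pos + n_neg > 0) 100 * n_pos / (n_pos + n_neg) else {
    flag <- "no viable tumor cells"
    NA_real_
  }
  structure(list(slide_id = slide_id, n_positive = n_pos,
                 n_negative = n_neg, n_excluded = n_exc, tps = tps,
                 category = categorize_tps(tps), flag = flag,
                 n_patches_used = used),
            class = "slide_score")
}

#' @export
print.slide_score <- function(x, ...) {
  cat(sprintf("<slide_score %s> P=%d N=%d excluded=%d TPS=%s (%s)%s\n",
              x$slide_id, x$n_positive, x$n_negative, x$n_excluded,
              ifelse(is.na(x$tps), "NA", sprintf("%.2f%%", x$tps)),
              as.character(x$category),
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Multi-class classification metrics
#'
#' Per-class one-vs-rest confusion counts and the standard derived
#' metrics: precision TP/(TP+FP), recall (TPR) TP/(TP+FN), specificity
#' TN/(TN+FP), FPR = 1 - specificity, F1 = 2PR/(P+R), accuracy
#' (TP+TN)/total. Zero-denominator metrics are 0 with a warning. The
#' weighted block is the support-weighted mean over classes; overall
#' accuracy is the plain fraction correct.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class order (default sorted union).
#' @return list of class `metrics_bundle`: `per_class` data.frame,
#'   `weighted`, `macro`, `accuracy`, `confusion`.
#' @export
classification_metrics <- function(y_true, y_pred, classes = NULL) {
  if (!length(y_true) || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be equal-length, non-empty")
  if (is.null(classes)) classes <- sort(unique(c(as.character(y_true),
                                                 as.character(y_pred))))
  yt <- factor(as.character(y_true), levels = classes)
  yp <- factor(as.character(y_pred), levels = classes)
  cm <- table(truth = yt, pred = yp)
  total <- length(yt)
  safe <- function(num, den) {
    if (den == 0) { warning("zero denominator in metric; reporting 0"); 0 }
    else num / den
  }
  rows <- lapply(classes, function(cl) {
    TP <- cm[cl, cl]
    FP <- sum(cm[, cl]) - TP
    FN <- sum(cm[cl, ]) - TP
    TN <- total - TP - FP - FN
    pr <- safe(TP, TP + FP)
    rc <- safe(TP, TP + FN)
    data.frame(class = cl, support = TP + FN, tp = TP, fp = FP, fn = FN,
               tn = TN, precision = pr, recall = rc,
               specificity = safe(TN, TN + FP),
               fpr = 1 - safe(TN, TN + FP),
               f1 = if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc),
               accuracy = (TP + TN) / total, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  w <- per_class$support / sum(per_class$support)
  agg <- function(col, weights) sum(per_class[[col]] * weights)
  mk <- function(weights)
    list(precision = agg("precision", weights),
         recall = agg("recall", weights),
         specificity = agg("specificity", weights),
         fpr = agg("fpr", weights), f1 = agg("f1", weights))
  structure(list(per_class = per_class, weighted = mk(w),
                 macro = mk(rep(1 / nrow(per_class), nrow(per_class))),
                 accuracy = sum(diag(cm)) / total, confusion = cm,
                 n_classes = length(classes)),
            class = "metrics_bundle")
}

#' Segmentation metrics for three-class region masks
#'
#' One-vs-rest IoU, DSC, TPR, FPR and specificity for the two tumor
#' classes (1 positive, 2 negative); the overall IoU/DSC is their
#' unweighted mean, and pixel accuracy is computed over all three
#' classes. A class absent from both masks scores IoU = DSC = 1 by
#' convention (message logged).
#'
#' @param true_mask,pred_mask integer matrices of identical shape with
#'   values 0/1/2.
#' @return list of class `metrics_bundle` with `per_class` (rows
#'   `positive`, `negative`), `overall` (`iou`, `dsc`), `pixel_accuracy`.
#' @export
segmentation_metrics <- function(true_mask, pred_mask) {
  stopifnot(all(dim(true_mask) == dim(pred_mask)))
  rows <- lapply(c(positive = 1L, negative = 2L), function(cl) {
    A <- true_mask == cl
    B <- pred_mask == cl
    inter <- sum(A & B)
    uni <- sum(A | B)
    TP <- inter
    FP <- sum(!A & B)
    FN <- sum(A & !B)
    TN <- sum(!A & !B)
    if (uni == 0) {
      message("class ", cl, " absent in both masks; IoU/DSC = 1 by ",
              "convention")
      iou <- 1; dsc <- 1
    } else {
      iou <- inter / uni
      dsc <- 2 * inter / (sum(A) + sum(B))
    }
    data.frame(class = cl, iou = iou, dsc = dsc,
               tpr = if (TP + FN == 0) 1 else TP / (TP + FN),
               fpr = if (FP + TN == 0) 0 else FP / (FP + TN),
               specificity = if (TN + FP == 0) 1 else TN / (TN + FP))
  })
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- c("positive", "negative")
  structure(list(per_class = per_class,
                 overall = list(iou = mean(per_class$iou),
                                dsc = mean(per_class$dsc)),
                 pixel_accuracy = mean(true_mask == pred_mask),
                 n_classes = 3L),
            class = "metrics_bundle")
}

#' Slide-level agreement between predicted and true TPS
#'
#' Pearson correlation and MAE on the TPS values, the 3x3 confusion
#' matrix over clinical categories, per-level accuracy (the recall of
#' each level), overall accuracy and both macro and weighted F1. Slides
#' with undefined (NA) TPS on either side are dropped with a message.
#'
#' @param pred_tps,true_tps numeric TPS vectors (percent), equal length.
#' @return list of class `slide_agreement`.
#' @export
slide_agreement <- function(pred_tps, true_tps) {
  stopifnot(length(pred_tps) == length(true_tps))
  ok <- !is.na(pred_tps) & !is.na(true_tps)
  if (any(!ok)) message(sum(!ok), " slide(s) with undefined TPS dropped")
  pred_tps <- pred_tps[ok]; true_tps <- true_tps[ok]
  if (length(pred_tps) < 2)
    stop("need at least 2 slides with defined TPS")
  r <- if (sd(pred_tps) == 0 || sd(true_tps) == 0) {
    message("constant TPS vector; correlation undefined")
    NA_real_
  } else cor(pred_tps, true_tps)
  pc <- categorize_tps(pred_tps)
  tc <- categorize_tps(true_tps)
  cm <- table(truth = tc, pred = pc)
  per_level <- diag(cm) / pmax(rowSums(cm), 1)
  cmet <- classification_metrics(as.character(tc), as.character(pc),
                                 classes = levels(tc))
  structure(list(pearson_r = r, mae = mean(abs(pred_tps - true_tps)),
                 confusion = cm, per_level_accuracy = per_level,
                 overall_accuracy = mean(pc == tc),
                 f1_macro = cmet$macro$f1, f1_weighted = cmet$weighted$f1,
                 n = length(pred_tps)),
            class = "slide_agreement")
}

#' @export
print.slide_agreement <- function(x, ...) {
  cat(sprintf(paste0("<slide_agreement> n=%d r=%.4f MAE=%.2f ",
                     "accuracy=%.3f macro-F1=%.3f\n"),
              x$n, x$pearson_r, x$mae, x$overall_accuracy, x$f1_macro))
  print(x$confusion)
  invisible(x)
}
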