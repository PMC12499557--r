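#' Desk-scale synthetic end-to-end benchmark
#'
#' Reruns the package's scaled stand-in for the full-slide experiment
#' from scratch: generate a synthetic cohort spanning the three clinical
#' TPS strata, train the three stage models on a held-out training split
#' (at most `epochs` epochs each), score the evaluation slides through
#' the full pipeline, and compare predicted with true TPS.
#'
#' The training recipe is the package's desk-scale configuration (see the
#' methods vignette): classifier at 64 px input, Self-ONN DeepLabV3+ at
#' 96 px input with cross-entropy + soft-Dice loss and uniform class
#' weights, star-convex detector with widened head, all with Adam at
#' learning rate 3e-3.
#'
#' @param seed integer seed driving cohort generation, fold assignment
#'   and training.
#' @param n_eval number of evaluation slides (default 30).
#' @param n_train number of training slides (default 20).
#' @param epochs epoch cap for every model (default 10).
#' @param patch_size tile size for the 512 px synthetic slides.
#' @param verbose print stage progress.
#' @return list with `agreement` (a [slide_agreement()]), `scores`
#'   data.frame (slide_id, pred_tps, true_tps, pred_category,
#'   true_category), `models`, `val_metrics` (classifier weighted F1 and
#'   pooled segmentation DSC on the validation fold), and `cohort_seed`.
#' @export
synthetic_benchmark <- function(seed = 1, n_eval = 30, n_train = 20,
                                epochs = 10, patch_size = 128,
                                verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  cfg <- synth_config(n_slides = n_eval + n_train,
                      patch_size = patch_size, seed = seed)
  say("generating ", cfg$n_slides, " synthetic slides")
  slides <- generate_cohort(cfg)
  eval_sl <- slides[seq_len(n_eval)]
  train_sl <- slides[n_eval + seq_len(n_train)]

  recs <- do.call(rbind, lapply(train_sl, function(s)
    tile_slide(s$image, s$region_mask, patch_size,
               min_tumor_pixels = 400, slide_id = s$slide_id)))
  folds <- assign_folds(vapply(train_sl, `[[`, character(1), "slide_id"),
                        5, seed = mix_seed(seed, 2))
  man <- build_manifests(recs, folds)
  say(nrow(man$classification), " training patches (",
      nrow(man$segmentation), " tumor)")

  hseed <- mix_seed(seed, 3)
  say("training patch classifier")
  cls <- build_classifier(input_size = 64, base = 8, seed = hseed)
  cfit <- suppressWarnings(train_model(cls, man$classification, fold = 1,
    hyper = list(lr = 3e-3, epochs = min(8, epochs), batch = 4,
                 seed = hseed)))
  say("  validation weighted F1 = ", round(cfit$val_metric, 4))

  say("training Self-ONN DeepLabV3+ segmenter")
  # two random restarts; keep the initialisation with the better
  # validation DSC (short-schedule training is sensitive to the init)
  sfit <- NULL
  for (r in 0:1) {
    seg <- build_segmentation_model("deeplabv3plus_selfonn",
                                    input_size = 96, base = 12,
                                    q_order = 3, seed = hseed + r)
    fit_r <- suppressWarnings(train_model(seg, man$segmentation, fold = 1,
      hyper = list(lr = 3e-3, epochs = epochs, batch = 4,
                   seed = hseed + r, class_weights = c(1, 1, 1))))
    say("  restart ", r, ": validation pooled tumor DSC = ",
        round(fit_r$val_metric, 4))
    if (is.null(sfit) || fit_r$val_metric > sfit$val_metric) sfit <- fit_r
  }

  say("training star-convex nucleus detector")
  det <- build_detector(star_geometry(32), base = 8, seed = hseed)
  dsub <- train_sl[seq_len(min(12, length(train_sl)))]
  dfit <- train_detector(det,
    lapply(dsub, function(s) nuclei_preprocess(s$image)),
    lapply(dsub, `[[`, "instance_mask"),
    hyper = list(lr = 3e-3, epochs = epochs, crop = 64,
                 crops_per_image = 10, radii_weight = 1, seed = hseed))

  models <- list(cls = cfit$model, seg = sfit$model, det = dfit$model)

  # detection audit on a few held-out slides: slide-level count ratio and
  # fraction of detections within 3 px of a true centroid
  detection <- do.call(rbind, lapply(eval_sl[seq_len(min(3, n_eval))],
                                     function(s) {
    d <- detect_nuclei(models$det, s$image)
    truth <- as.matrix(s$centroids[, c("row", "col")])
    matched <- 0
    if (nrow(d) > 0 && nrow(truth) > 0) {
      for (k in seq_len(nrow(d))) {
        dmin <- min(sqrt((truth[, 1] - d$row[k])^2 +
                           (truth[, 2] - d$col[k])^2))
        if (dmin <= 3) matched <- matched + 1
      }
    }
    data.frame(slide_id = s$slide_id, n_true = nrow(truth),
               n_detected = nrow(d),
               match_rate = matched / max(nrow(d), 1))
  }))

  say("scoring ", n_eval, " held-out slides")
  pred <- vapply(eval_sl, function(s)
    score_slide(s, models, patch_size = patch_size)$tps, numeric(1))
  truth <- vapply(eval_sl, `[[`, numeric(1), "true_tps")
  ag <- slide_agreement(pred, truth)
  scores <- data.frame(
    slide_id = vapply(eval_sl, `[[`, character(1), "slide_id"),
    pred_tps = pred, true_tps = truth,
    pred_category = as.character(categorize_tps(pred)),
    true_category = as.character(categorize_tps(truth)),
    stringsAsFactors = FALSE)
  list(agreement = ag, scores = scores, models = models,
       val_metrics = list(cls_weighted_f1 = cfit$val_metric,
                          seg_pooled_dsc = sfit$val_metric),
       detection = detection, cohort_seed = seed)
}
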