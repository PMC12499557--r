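#' Default pipeline configuration
#'
#' Full-scale defaults follow the source protocol: 1000x1000 patches,
#' non-overlapping stride, inputs resized to 224 (classification) and 256
#' (segmentation), Adam at learning rate 1e-4, 100 epochs, 5 slide-level
#' folds, 32 detector rays, and the three clinical TPS bins. Demo/test
#' configurations override sizes and epochs downward.
#'
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    paths = list(slides = NULL, masks = NULL, out = "pdl1tps_out"),
    synth = list(n_slides = 12, slide_size = c(512, 512),
                 cells_per_slide = NULL, nucleus_radius = NULL, seed = 1),
    tiling = list(patch_size = 1000, stride = 1000, min_tumor_pixels = 1),
    training = list(lr = 1e-4, epochs = 100, batch = 4, seed = 1,
                    folds = 5, val_fold = 1, cls_input = 224,
                    seg_input = 256, seg_arch = "deeplabv3plus_selfonn",
                    base = 8, q_order = 3),
    stain = list(blur_sigma = 1.0, matrix = NULL),
    detector = list(n_rays = 32, prob_thresh = 0.5, iou_thresh = 0.4,
                    crop = 64, checkpoint = NULL),
    scoring = list(assignment = "centroid", segment_all = FALSE)),
    class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks schema and value constraints before any compute; errors name
#' the offending key path.
#'
#' @param cfg a configuration list (class `run_config` or plain list).
#' @return the validated config, invisibly classed `run_config`.
#' @export
validate_config <- function(cfg) {
  base <- default_config()
  # stride defaults to the configured patch size (non-overlapping tiles)
  if (is.null(cfg$tiling$stride) && !is.null(cfg$tiling$patch_size))
    cfg$tiling$stride <- cfg$tiling$patch_size
  for (sec in names(base))
    for (k in names(base[[sec]]))
      if (is.null(cfg[[sec]][[k]]) && !is.null(base[[sec]][[k]]))
        cfg[[sec]][[k]] <- base[[sec]][[k]]
  chk <- function(cond, key, msg)
    if (!cond) stop("config ", key, ": ", msg, call. = FALSE)
  chk(cfg$tiling$patch_size > 0, "tiling.patch_size", "must be positive")
  chk(cfg$tiling$stride > 0, "tiling.stride", "must be positive")
  chk(cfg$training$folds >= 2, "training.folds", "must be >= 2")
  chk(cfg$training$lr > 0, "training.lr", "must be positive")
  chk(cfg$training$epochs >= 1, "training.epochs", "must be >= 1")
  chk(cfg$detector$n_rays >= 3, "detector.n_rays", "must be >= 3")
  chk(cfg$detector$prob_thresh > 0 && cfg$detector$prob_thresh < 1,
      "detector.prob_thresh", "must be in (0, 1)")
  chk(cfg$detector$iou_thresh > 0 && cfg$detector$iou_thresh < 1,
      "detector.iou_thresh", "must be in (0, 1)")
  class(cfg) <- "run_config"
  invisible(cfg)
}

#' Read/write a configuration as YAML
#' @param path YAML file.
#' @return for `read_config`, a validated `run_config`.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the model object (architecture spec and
#' weights together).
#'
#' @param model any model object (`cls_model`, `seg_model`,
#'   `star_detector`).
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}

synth_cfg_from <- function(cfg) {
  args <- list(n_slides = cfg$synth$n_slides,
               slide_size = cfg$synth$slide_size,
               patch_size = cfg$tiling$patch_size,
               seed = cfg$synth$seed)
  if (!is.null(cfg$synth$cells_per_slide))
    args$cells_per_slide <- cfg$synth$cells_per_slide
  if (!is.null(cfg$synth$nucleus_radius))
    args$nucleus_radius <- cfg$synth$nucleus_radius
  do.call(synth_config, args)
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", sep = "")
  if (!is.null(log_path)) cat(msg, "\n", sep = "", file = log_path,
                              append = TRUE)
}

# Tile a list of synth slides into classification/segmentation manifests.
cohort_manifests <- function(slides, patch_size, stride, n_folds,
                             seed, min_tumor_pixels = 1) {
  recs <- do.call(rbind, lapply(slides, function(s)
    tile_slide(s$image, s$region_mask, patch_size, stride,
               min_tumor_pixels, slide_id = s$slide_id)))
  folds <- assign_folds(vapply(slides, `[[`, character(1), "slide_id"),
                        n_folds, seed)
  c(build_manifests(recs, folds), list(folds = folds))
}

# guarantee non-empty train/val splits for a manifest; degenerate tiny
# cohorts fall back to an alternating row split (checkpoint selection
# only), with a log note
ensure_split <- function(manifest, val_fold, log_path = NULL) {
  if (nrow(manifest) == 0) return(manifest)
  if (any(manifest$fold == val_fold) && any(manifest$fold != val_fold))
    return(manifest)
  log_line(log_path, "fold ", val_fold, " split degenerate; ",
           "falling back to row-alternating validation split")
  manifest$fold <- rep(c(val_fold + 1, val_fold),
                       length.out = nrow(manifest))
  manifest
}

train_stage_models <- function(slides, cfg, log_path = NULL) {
  tr <- cfg$training
  man <- cohort_manifests(slides, cfg$tiling$patch_size, cfg$tiling$stride,
                          tr$folds, tr$seed, cfg$tiling$min_tumor_pixels)
  man$classification <- ensure_split(man$classification, tr$val_fold,
                                     log_path)
  man$segmentation <- ensure_split(man$segmentation, tr$val_fold,
                                   log_path)
  log_line(log_path, "manifests: ", nrow(man$classification),
           " patches, ", nrow(man$segmentation), " tumor patches")
  hy <- list(lr = tr$lr, epochs = tr$epochs, batch = tr$batch,
             seed = tr$seed)
  cls <- build_classifier(input_size = tr$cls_input, base = tr$base,
                          seed = tr$seed)
  cls_fit <- train_model(cls, man$classification, tr$val_fold, hy)
  log_line(log_path, "classifier val weighted F1 = ",
           round(cls_fit$val_metric, 4))
  seg <- build_segmentation_model(tr$seg_arch, input_size = tr$seg_input,
                                  base = tr$base, q_order = tr$q_order,
                                  seed = tr$seed)
  seg_fit <- train_model(seg, man$segmentation, tr$val_fold, hy)
  log_line(log_path, "segmentation val mean tumor DSC = ",
           round(seg_fit$val_metric, 4))
  det <- build_detector(star_geometry(cfg$detector$n_rays),
                        base = tr$base, seed = tr$seed)
  train_sl <- slides[vapply(slides, function(s)
    man$folds$fold[man$folds$slide_id == s$slide_id] != tr$val_fold,
    logical(1))]
  imgs <- lapply(train_sl, function(s)
    nuclei_preprocess(s$image, blur_sigma = cfg$stain$blur_sigma))
  msks <- lapply(train_sl, `[[`, "instance_mask")
  det_fit <- train_detector(det, imgs, msks,
                            list(lr = tr$lr, epochs = tr$epochs,
                                 crop = cfg$detector$crop, seed = tr$seed))
  log_line(log_path, "detector final loss = ",
           round(utils::tail(det_fit$history$loss, 1), 4))
  list(cls = cls_fit$model, seg = seg_fit$model, det = det_fit$model,
       manifests = man)
}

score_cohort <- function(slides, models, cfg) {
  lapply(slides, function(s)
    score_slide(s, models, patch_size = cfg$tiling$patch_size,
                stride = cfg$tiling$stride,
                segment_all = cfg$scoring$segment_all,
                prob_thresh = cfg$detector$prob_thresh,
                iou_thresh = cfg$detector$iou_thresh,
                blur_sigma = cfg$stain$blur_sigma))
}

scores_to_df <- function(scores) {
  data.frame(slide_id = vapply(scores, `[[`, character(1), "slide_id"),
             n_positive = vapply(scores, `[[`, numeric(1), "n_positive"),
             n_negative = vapply(scores, `[[`, numeric(1), "n_negative"),
             tps = vapply(scores, `[[`, numeric(1), "tps"),
             category = vapply(scores, function(s)
               as.character(s$category), character(1)),
             flag = vapply(scores, function(s) s$flag %||% "",
                           character(1)),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on one configuration
#'
#' Synthesize (or load) slides, tile, train the three stage models, score
#' every slide and write manifests, checkpoints, per-slide scores and an
#' agreement report to a deterministic directory layout under
#' `cfg$paths$out`.
#'
#' @param cfg a `run_config`, plain list, or YAML path.
#' @param slides optional pre-generated list of `synth_slide`s (overrides
#'   `cfg$synth` / `cfg$paths$slides`).
#' @return list with `scores` (data.frame), `report`, `models`, and the
#'   output directory.
#' @export
run_pipeline <- function(cfg = default_config(), slides = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  cfg <- validate_config(cfg)
  out <- cfg$paths$out
  for (d in c("", "manifests", "checkpoints", "scores"))
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  if (is.null(slides)) {
    scfg <- synth_cfg_from(cfg)
    log_line(log_path, "synthesizing ", scfg$n_slides, " slides")
    slides <- generate_cohort(scfg)
  }
  models <- train_stage_models(slides, cfg, log_path)
  write.csv(models$manifests$classification[
    !vapply(models$manifests$classification, is.list, logical(1))],
    file.path(out, "manifests", "classification.csv"), row.names = FALSE)
  write.csv(models$manifests$segmentation[
    !vapply(models$manifests$segmentation, is.list, logical(1))],
    file.path(out, "manifests", "segmentation.csv"), row.names = FALSE)
  save_checkpoint(models$cls, file.path(out, "checkpoints", "cls.rds"))
  save_checkpoint(models$seg, file.path(out, "checkpoints", "seg.rds"))
  save_checkpoint(models$det, file.path(out, "checkpoints", "det.rds"))
  log_line(log_path, "scoring ", length(slides), " slides")
  scores <- score_cohort(slides, models, cfg)
  sdf <- scores_to_df(scores)
  write.csv(sdf, file.path(out, "scores", "slide_scores.csv"),
            row.names = FALSE)
  report <- NULL
  truth <- vapply(slides, function(s) s$true_tps %||% NA_real_, numeric(1))
  if (any(!is.na(truth))) {
    ag <- tryCatch(slide_agreement(sdf$tps, truth), error = identity)
    report <- if (inherits(ag, "error")) {
      log_line(log_path, "agreement unavailable: ", conditionMessage(ag))
      list(n_slides = length(slides), note = conditionMessage(ag))
    } else {
      log_line(log_path, sprintf("agreement: r=%.4f MAE=%.2f acc=%.3f",
                                 ag$pearson_r, ag$mae,
                                 ag$overall_accuracy))
      list(n_slides = ag$n, pearson_r = ag$pearson_r, mae = ag$mae,
           confusion = as.vector(t(ag$confusion)),
           per_level_accuracy = as.list(ag$per_level_accuracy),
           overall_accuracy = ag$overall_accuracy,
           f1_macro = ag$f1_macro, f1_weighted = ag$f1_weighted)
    }
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(scores = sdf, report = report, models = models[c("cls", "seg",
                                                        "det")],
       out = out)
}

#' Slide-level cross-validation
#'
#' Each fold is held out once: the three stage models are trained on the
#' remaining slides (one training fold serves as the validation split for
#' checkpoint selection) and the held-out slides are scored by models
#' that never saw them. Returns per-fold reports, the pooled agreement
#' over all test scores, and the per-fold training manifests for leakage
#' auditing.
#'
#' @param cfg a `run_config` (or list/YAML path).
#' @param slides list of `synth_slide`s; generated from `cfg$synth` if
#'   NULL.
#' @return list with `scores` (pooled data.frame with fold column),
#'   `pooled` (`slide_agreement`), `per_fold`, `train_slide_ids` (list of
#'   character vectors per fold).
#' @export
crossvalidate <- function(cfg = default_config(), slides = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  cfg <- validate_config(cfg)
  if (is.null(slides)) slides <- generate_cohort(synth_cfg_from(cfg))
  ids <- vapply(slides, `[[`, character(1), "slide_id")
  n_folds <- cfg$training$folds
  folds <- assign_folds(ids, n_folds, cfg$training$seed)
  all_scores <- list()
  per_fold <- list()
  train_ids <- list()
  for (f in seq_len(n_folds)) {
    test_ids <- folds$slide_id[folds$fold == f]
    tr_slides <- slides[!ids %in% test_ids]
    te_slides <- slides[ids %in% test_ids]
    fold_cfg <- cfg
    fold_cfg$training$folds <- max(2, n_folds - 1)
    fold_cfg$training$val_fold <- 1
    models <- train_stage_models(tr_slides, fold_cfg)
    leak <- intersect(unique(models$manifests$classification$slide_id),
                      test_ids)
    if (length(leak))
      stop("leakage: test slides in training manifest: ",
           paste(leak, collapse = ", "))
    train_ids[[f]] <- unique(models$manifests$classification$slide_id)
    scores <- score_cohort(te_slides, models, cfg)
    sdf <- scores_to_df(scores)
    sdf$fold <- f
    sdf$true_tps <- vapply(te_slides, `[[`, numeric(1), "true_tps")
    all_scores[[f]] <- sdf
    per_fold[[f]] <- sdf
  }
  pooled_df <- do.call(rbind, all_scores)
  pooled <- tryCatch(slide_agreement(pooled_df$tps, pooled_df$true_tps),
                     error = function(e) {
                       message("pooled agreement unavailable: ",
                               conditionMessage(e))
                       NULL
                     })
  list(scores = pooled_df, pooled = pooled, per_fold = per_fold,
       train_slide_ids = train_ids)
}
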