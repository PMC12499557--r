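# Stage-1 classifier and stage-2 segmentation networks, built on the
# nn_core engine. All models are fully convolutional; spatial sizes must
# be divisible by 4 (UNet) or 8 (DeepLabV3+).

lay_fwd <- function(p, x) if (!is.null(p$q)) selfonn_fwd(p, x) else conv_fwd(p, x)
lay_bwd <- function(p, cache, dy)
  if (!is.null(p$q)) selfonn_bwd(p, cache, dy) else conv_bwd(p, cache, dy)

make_layer <- function(kind, cin, cout, k = 3, stride = 1, dilation = 1,
                       q = 3, squash = "tanh") {
  if (kind == "selfonn")
    nn_selfonn_init(cin, cout, k, q = q, stride = stride,
                    dilation = dilation, squash = squash)
  else nn_conv_init(cin, cout, k, stride = stride, dilation = dilation)
}

resize_arr <- function(x, size_r, size_c = size_r, nearest = FALSE) {
  d <- dim(x)
  if (d[1] == size_r && d[2] == size_c) return(x)
  out <- EBImage::resize(x, w = size_r, h = size_c,
                         filter = if (nearest) "none" else "bilinear")
  out <- as.array(out)
  dim(out) <- if (length(d) == 3) c(size_r, size_c, d[3]) else
    c(size_r, size_c)
  out
}

# ---- classifier ----------------------------------------------------------

#' Build the stage-1 tumor/non-tumor patch classifier
#'
#' The mandatory backbone is `"small_cnn"`, a compact CPU-trainable
#' network: four stride-2 3x3 conv+ReLU stages, global average pooling and
#' a linear head to 2 classes. Patches are resized to `input_size`
#' (default 224) and scaled to `[0, 1]` at prediction time. Larger
#' pretrained backbones are out of scope here; unknown names raise an
#' error listing the available options.
#'
#' @param backbone backbone name, `"small_cnn"`.
#' @param input_size square input size in pixels, default 224.
#' @param base base channel width, default 8.
#' @param seed weight-initialisation seed.
#' @return model object of class `cls_model`.
#' @export
build_classifier <- function(backbone = "small_cnn", input_size = 224,
                             base = 8, seed = 1L) {
  avail <- c("small_cnn")
  if (!backbone %in% avail)
    stop("unknown backbone '", backbone, "'; available: ",
         paste(avail, collapse = ", "))
  C <- base
  params <- with_seed(seed, list(
    c1 = nn_conv_init(3, C, 3, stride = 2),
    c2 = nn_conv_init(C, 2 * C, 3, stride = 2),
    c3 = nn_conv_init(2 * C, 4 * C, 3, stride = 2),
    c4 = nn_conv_init(4 * C, 4 * C, 3, stride = 2),
    fc = list(W = matrix(rnorm(4 * C * 2, 0, sqrt(1 / (4 * C))), 4 * C, 2),
              b = numeric(2))))
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 base = C, n_classes = 2L, params = params,
                 classes = c("non-tumor", "tumor")),
            class = "cls_model")
}

cls_forward <- function(model, x) {
  p <- model$params
  cache <- list()
  h <- x - 0.5   # center [0,1] inputs

  for (nm in c("c1", "c2", "c3", "c4")) {
    cc <- conv_fwd(p[[nm]], h)
    r <- relu_fwd(cc$y)
    cache[[nm]] <- list(conv = cc, mask = r$mask)
    h <- r$y
  }
  g <- apply(h, 3, mean)
  logits <- as.numeric(g %*% p$fc$W + p$fc$b)
  cache$g <- g
  cache$hdim <- dim(h)
  list(logits = logits, prob = { e <- exp(logits - max(logits)); e / sum(e) },
       cache = cache)
}

cls_backward <- function(model, cache, dlogits) {
  p <- model$params
  grads <- list(fc = list(W = outer(cache$g, dlogits), b = dlogits))
  dg <- as.numeric(p$fc$W %*% dlogits)
  hd <- cache$hdim
  dh <- array(rep(dg / (hd[1] * hd[2]), each = hd[1] * hd[2]), hd)
  for (nm in c("c4", "c3", "c2", "c1")) {
    dh <- relu_bwd(list(mask = cache[[nm]]$mask), dh)
    g <- conv_bwd(p[[nm]], cache[[nm]]$conv, dh)
    grads[[nm]] <- g$grads
    dh <- g$dx
  }
  grads
}

#' Classify one patch as tumor or non-tumor
#'
#' Deterministic at inference; the patch is resized to the model's input
#' size and scaled to `[0, 1]`.
#'
#' @param model a [build_classifier()] model (trained or not).
#' @param image RGB patch array (H, W, 3), values 0-255.
#' @return list with `label` (`"tumor"`/`"non-tumor"`) and `prob`, the
#'   probability of the predicted class.
#' @export
predict_patch_class <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an RGB patch with 3 channels")
  x <- resize_arr(image / 255, model$input_size)
  fw <- cls_forward(model, x)
  k <- which.max(fw$prob)
  list(label = model$classes[k], prob = fw$prob[k],
       prob_tumor = fw$prob[2])
}

# ---- UNet trunk (shared by segmentation UNet and the nucleus detector) ---

unet_init <- function(cin, C, kind = "conv", q = 3, squash = "tanh") {
  L <- function(ci, co, k = 3, s = 1)
    make_layer(kind, ci, co, k, stride = s, q = q, squash = squash)
  list(e1 = L(cin, C), d1 = L(C, 2 * C, s = 2), e2 = L(2 * C, 2 * C),
       d2 = L(2 * C, 4 * C, s = 2), bneck = L(4 * C, 4 * C),
       u1 = L(6 * C, 2 * C), u2 = L(3 * C, C), head = L(C, C))
}

unet_trunk_fwd <- function(p, x) {
  cc <- list()
  step <- function(nm, inp) {
    c1 <- lay_fwd(p[[nm]], inp)
    r <- relu_fwd(c1$y)
    cc[[nm]] <<- list(conv = c1, mask = r$mask)
    r$y
  }
  e1 <- step("e1", x)
  e2 <- step("e2", step("d1", e1))
  b <- step("bneck", step("d2", e2))
  u1 <- step("u1", concat_ch(up_nn(b, 2), e2))
  u2 <- step("u2", concat_ch(up_nn(u1, 2), e1))
  feat <- step("head", u2)
  list(feat = feat, cache = cc, C = dim(e1)[3])
}

unet_trunk_bwd <- function(p, fw, dfeat) {
  cc <- fw$cache
  C <- fw$C
  grads <- list()
  back <- function(nm, dy) {
    dy <- relu_bwd(list(mask = cc[[nm]]$mask), dy)
    g <- lay_bwd(p[[nm]], cc[[nm]]$conv, dy)
    grads[[nm]] <<- g$grads
    g$dx
  }
  du2 <- back("head", dfeat)
  dcat2 <- back("u2", du2)
  s2 <- split_ch(dcat2, 2 * C)
  du1 <- up_nn_bwd(s2$a, 2)
  de1_skip <- s2$b
  dcat1 <- back("u1", du1)
  s1 <- split_ch(dcat1, 4 * C)
  db <- up_nn_bwd(s1$a, 2)
  de2_skip <- s1$b
  dd2 <- back("bneck", db)
  de2 <- back("d2", dd2) + de2_skip
  dd1 <- back("e2", de2)
  de1 <- back("d1", dd1) + de1_skip
  dx <- back("e1", de1)
  list(dx = dx, grads = grads)
}

# ---- segmentation models -------------------------------------------------

#' Build a three-class tumor-region segmentation model
#'
#' Architectures: `"unet"` (small UNet), `"unet_encoder"` (UNet with a
#' pluggable encoder width from a registry of CPU-scale encoders),
#' `"deeplabv3plus"` (compact DeepLabV3+: stride-8 backbone, ASPP with
#' dilated branches and image pooling, low-level skip decoder), and
#' `"deeplabv3plus_selfonn"` — the same DeepLabV3+ graph with every
#' convolutional position (backbone, ASPP, decoder) replaced by a Self-ONN
#' layer of order `q_order`. Output is a per-pixel probability simplex
#' over classes 0 (non-tumor), 1 (positive tumor), 2 (negative tumor) at
#' the input resolution.
#'
#' @param architecture one of the four names above.
#' @param encoder encoder name for `"unet_encoder"`; registry:
#'   `"small"` (base width), `"wide"` (double width).
#' @param n_classes number of classes, default 3.
#' @param input_size square model resolution, default 256.
#' @param base base channel width, default 8.
#' @param q_order Self-ONN Taylor order Q, default 3.
#' @param seed weight-initialisation seed.
#' @return model object of class `seg_model`.
#' @export
build_segmentation_model <- function(architecture = c("unet", "unet_encoder",
                                                      "deeplabv3plus",
                                                      "deeplabv3plus_selfonn"),
                                     encoder = "small", n_classes = 3,
                                     input_size = 256, base = 8,
                                     q_order = 3, seed = 1L) {
  architecture <- match.arg(architecture)
  C <- base
  if (architecture == "unet_encoder") {
    registry <- c(small = 1, wide = 2)
    if (!encoder %in% names(registry))
      stop("unknown encoder '", encoder, "'; available: ",
           paste(names(registry), collapse = ", "))
    C <- base * registry[[encoder]]
  }
  kind <- if (architecture == "deeplabv3plus_selfonn") "selfonn" else "conv"
  params <- with_seed(seed, {
    if (architecture %in% c("unet", "unet_encoder")) {
      tr <- unet_init(3, C)
      tr$out <- nn_conv_init(C, n_classes, 1)
      tr
    } else {
      L <- function(ci, co, k = 3, s = 1, d = 1)
        make_layer(kind, ci, co, k, stride = s, dilation = d, q = q_order)
      list(b1 = L(3, C, s = 2), b2 = L(C, 2 * C, s = 2),
           b3 = L(2 * C, 4 * C, s = 2), b4 = L(4 * C, 4 * C),
           aspp1 = L(4 * C, 2 * C, k = 1),
           aspp2 = L(4 * C, 2 * C, d = 2),
           aspp3 = L(4 * C, 2 * C, d = 4),
           asppP = L(4 * C, 2 * C, k = 1),
           asppproj = L(8 * C, 2 * C, k = 1),
           lowproj = L(2 * C, C, k = 1),
           dec1 = L(3 * C, 2 * C),
           out = L(2 * C, n_classes, k = 1))
    }
  })
  structure(list(architecture = architecture, encoder = encoder,
                 n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size), base = C,
                 q_order = as.integer(q_order), params = params),
            class = "seg_model")
}

seg_forward <- function(model, x) {
  p <- model$params
  x <- x - 0.5   # center [0,1] inputs
  if (model$architecture %in% c("unet", "unet_encoder")) {
    tr <- unet_trunk_fwd(p, x)
    oc <- conv_fwd(p$out, tr$feat)
    return(list(logits = oc$y, prob = softmax_channels(oc$y),
                cache = list(trunk = tr, out = oc)))
  }
  cc <- list()
  step <- function(nm, inp, act = TRUE) {
    c1 <- lay_fwd(p[[nm]], inp)
    if (!act) {
      cc[[nm]] <<- list(conv = c1, mask = NULL)
      return(c1$y)
    }
    r <- relu_fwd(c1$y)
    cc[[nm]] <<- list(conv = c1, mask = r$mask)
    r$y
  }
  h1 <- step("b1", x)
  low <- step("b2", h1)
  h3 <- step("b3", low)
  h4 <- step("b4", h3)
  a1 <- step("aspp1", h4)
  a2 <- step("aspp2", h4)
  a3 <- step("aspp3", h4)
  gp <- apply(h4, 3, mean)
  gpc <- array(gp, c(1, 1, length(gp)))
  aP1 <- step("asppP", gpc)
  d4 <- dim(h4)
  aP <- array(rep(as.numeric(aP1), each = d4[1] * d4[2]),
              c(d4[1], d4[2], dim(aP1)[3]))
  acat <- concat_ch(concat_ch(a1, a2), concat_ch(a3, aP))
  aout <- step("asppproj", acat)
  lowp <- step("lowproj", low)
  dcat <- concat_ch(up_nn(aout, 2), lowp)
  dec <- step("dec1", dcat)
  lg4 <- step("out", dec, act = FALSE)
  logits <- up_nn(lg4, 4)
  cc$dims <- list(d4 = d4, C2 = dim(aout)[3])
  list(logits = logits, prob = softmax_channels(logits), cache = cc)
}

seg_backward <- function(model, cache, dlogits) {
  p <- model$params
  if (model$architecture %in% c("unet", "unet_encoder")) {
    g <- conv_bwd(p$out, cache$out, dlogits)
    tb <- unet_trunk_bwd(p, cache$trunk, g$dx)
    tb$grads$out <- g$grads
    return(tb$grads)
  }
  cc <- cache
  grads <- list()
  back <- function(nm, dy) {
    if (!is.null(cc[[nm]]$mask))
      dy <- relu_bwd(list(mask = cc[[nm]]$mask), dy)
    g <- lay_bwd(p[[nm]], cc[[nm]]$conv, dy)
    grads[[nm]] <<- g$grads
    g$dx
  }
  dlg4 <- up_nn_bwd(dlogits, 4)
  ddec <- back("out", dlg4)
  ddcat <- back("dec1", ddec)
  C2 <- cc$dims$C2
  sp <- split_ch(ddcat, C2)
  daout <- up_nn_bwd(sp$a, 2)
  dlowp <- sp$b
  dacat <- back("asppproj", daout)
  spl <- split_ch(dacat, 2 * C2)
  s12 <- split_ch(spl$a, C2)
  s34 <- split_ch(spl$b, C2)
  da1 <- s12$a; da2 <- s12$b; da3 <- s34$a; daP <- s34$b
  d4 <- cc$dims$d4
  # broadcast backward: sum over spatial, then GAP backward (mean)
  daP1 <- array(apply(daP, 3, sum), c(1, 1, dim(daP)[3]))
  dgpc <- back("asppP", daP1)
  dh4_gap <- array(rep(as.numeric(dgpc) / (d4[1] * d4[2]),
                       each = d4[1] * d4[2]), d4)
  dh4 <- back("aspp1", da1) + back("aspp2", da2) + back("aspp3", da3) +
    dh4_gap
  dlow_skip <- back("lowproj", dlowp)
  dh3 <- back("b4", dh4)
  dlow <- back("b3", dh3) + dlow_skip
  dh1 <- back("b2", dlow)
  back("b1", dh1)
  grads
}

#' Predict a three-class region mask for a patch
#'
#' Runs the segmentation model at its native resolution and upsamples the
#' per-pixel argmax back to the patch resolution with nearest-neighbor
#' interpolation.
#'
#' @param model a [build_segmentation_model()] model.
#' @param image RGB patch (H, W, 3), values 0-255.
#' @return integer matrix (H x W) with values 0 (non-tumor), 1 (positive
#'   tumor), 2 (negative tumor).
#' @export
predict_region_mask <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an RGB patch with 3 channels")
  x <- resize_arr(image / 255, model$input_size)
  fw <- seg_forward(model, x)
  am <- apply(fw$prob, c(1, 2), which.max) - 1L
  up <- resize_arr(am, d[1], d[2], nearest = TRUE)
  matrix(as.integer(round(up)), d[1], d[2])
}

#' Copy shared weights from a conv model into a Self-ONN model
#'
#' Sets the first-order kernel `W1` (and bias) of every Self-ONN layer to
#' the corresponding convolution weights and zeroes the higher orders, so
#' a Q=1 (or zero-higher-order) Self-ONN network computes exactly the same
#' function as its convolutional counterpart.
#'
#' @param conv_model,onn_model two structurally matching models (e.g.
#'   `deeplabv3plus` and `deeplabv3plus_selfonn`).
#' @return `onn_model` with transferred weights.
#' @export
share_weights_q1 <- function(conv_model, onn_model) {
  for (nm in names(conv_model$params)) {
    src <- conv_model$params[[nm]]
    dst <- onn_model$params[[nm]]
    if (is.null(src$kh)) next
    if (!is.null(dst$q)) {
      dst$W1 <- src$W
      dst$b <- src$b
      if (dst$q > 1)
        for (qi in 2:dst$q) dst[[paste0("W", qi)]] <-
          dst[[paste0("W", qi)]] * 0
    } else {
      dst$W <- src$W
      dst$b <- src$b
    }
    onn_model$params[[nm]] <- dst
  }
  onn_model
}

# ---- training ------------------------------------------------------------

manifest_patch <- function(row) {
  img <- if ("image" %in% names(row) && !is.null(row$image[[1]]))
    row$image[[1]] else read_slide_image(row$image_path)$image
  msk <- NULL
  if ("mask" %in% names(row) && !is.null(row$mask[[1]]))
    msk <- row$mask[[1]]
  else if ("mask_path" %in% names(row) && !is.na(row$mask_path))
    msk <- read_slide_image(row$image_path, row$mask_path)$region_mask
  list(image = img, mask = msk)
}

augment_patch <- function(img, msk) {
  if (runif(1) < 0.5) {
    img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
    if (!is.null(msk)) msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  k <- sample(0:3, 1)
  for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))[rev(seq_len(dim(img)[2])), , ,
                                  drop = FALSE]
    if (!is.null(msk)) msk <- t(msk)[rev(seq_len(ncol(msk))), , drop = FALSE]
  }
  list(image = img, mask = msk)
}

#' Train a classification or segmentation model
#'
#' Adam with the configured learning rate; the manifest is split into a
#' training set (rows whose `fold` differs from `fold`) and a validation
#' set (rows whose `fold` equals `fold`). The best epoch's weights are
#' kept, selected on weighted F1 (classification) or mean tumor-class DSC
#' (segmentation). Augmentation is limited to flips and 90-degree
#' rotations. Reproducible given `hyper$seed`.
#'
#' @param model a `cls_model` or `seg_model`.
#' @param manifest patch manifest (from [build_manifests()]); needs
#'   in-memory `image`/`mask` list-columns or `image_path`/`mask_path`.
#' @param fold validation fold index.
#' @param hyper list: `lr` (default 1e-4), `epochs` (default 10), `batch`
#'   (default 4), `seed` (default 1), `augment` (default TRUE),
#'   `class_weights` (segmentation; default balanced by inverse pixel
#'   frequency of the three classes over the training set).
#' @return list with `model` (best weights), `history` (per-epoch
#'   data.frame: epoch, loss, val_metric).
#' @export
train_model <- function(model, manifest, fold, hyper = list()) {
  lr <- hyper$lr %||% 1e-4
  epochs <- hyper$epochs %||% 10
  batch <- hyper$batch %||% 4
  seed <- hyper$seed %||% 1L
  augment <- hyper$augment %||% TRUE
  dice_w <- hyper$dice_weight %||% 1
  is_cls <- inherits(model, "cls_model")
  tr_idx <- which(manifest$fold != fold)
  va_idx <- which(manifest$fold == fold)
  if (!length(tr_idx) || !length(va_idx))
    stop("empty train or validation split for fold ", fold)
  with_seed(seed, {
    st <- adam_init(model$params)
    cw <- NULL
    if (!is_cls) {
      cw <- hyper$class_weights
      if (is.null(cw)) {
        cnt <- c(1, 1, 1)
        for (i in tr_idx[seq_len(min(20, length(tr_idx)))]) {
          m <- manifest_patch(manifest[i, ])$mask
          if (!is.null(m)) cnt <- cnt + tabulate(m + 1L, 3)
        }
        cw <- sum(cnt) / (3 * cnt)
      }
    }
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_metric = numeric(0))
    best <- list(metric = -Inf, params = model$params)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      tot_loss <- 0
      nb <- 0
      for (bs in seq(1, length(ord), by = batch)) {
        ids <- ord[bs:min(bs + batch - 1, length(ord))]
        gacc <- NULL
        for (i in ids) {
          pt <- manifest_patch(manifest[i, ])
          if (augment) pt <- augment_patch(pt$image, pt$mask)
          x <- resize_arr(pt$image / 255, model$input_size)
          if (is_cls) {
            fw <- cls_forward(model, x)
            tgt <- match(manifest$cls_label[i], model$classes)
            ls <- softmax_ce(fw$logits, tgt)
            g <- cls_backward(model, fw$cache, ls$dlogits)
          } else {
            tm <- resize_arr(pt$mask, model$input_size, nearest = TRUE)
            tm <- matrix(as.integer(round(tm)) + 1L, model$input_size,
                         model$input_size)
            fw <- seg_forward(model, x)
            ls <- softmax_ce(fw$logits, tm, class_weights = cw)
            # compound loss: cross-entropy + soft Dice on the tumor classes
            sd <- soft_dice(fw$prob, tm, classes = 2:3)
            ls$loss <- ls$loss + dice_w * sd$loss
            ls$dlogits <- ls$dlogits + dice_w * sd$dlogits
            g <- seg_backward(model, fw$cache, ls$dlogits)
          }
          tot_loss <- tot_loss + ls$loss
          gacc <- grads_add(gacc, g)
        }
        gacc <- grads_scale(gacc, 1 / length(ids))
        up <- adam_step(model$params, gacc, st, lr = lr)
        model$params <- up$params
        st <- up$state
        nb <- nb + 1
      }
      vm <- eval_model(model, manifest, va_idx)
      history <- rbind(history, data.frame(epoch = ep,
                                           loss = tot_loss / length(ord),
                                           val_metric = vm))
      if (vm >= best$metric) best <- list(metric = vm, params = model$params)
    }
    model$params <- best$params
    list(model = model, history = history, val_metric = best$metric)
  })
}

eval_model <- function(model, manifest, idx) suppressWarnings(suppressMessages({
  if (inherits(model, "cls_model")) {
    yt <- manifest$cls_label[idx]
    yp <- vapply(idx, function(i)
      predict_patch_class(model, manifest_patch(manifest[i, ])$image)$label,
      character(1))
    classification_metrics(yt, yp, classes = model$classes)$weighted$f1
  } else {
    tms <- list(); pms <- list()
    for (i in idx) {
      pt <- manifest_patch(manifest[i, ])
      tms[[length(tms) + 1]] <- pt$mask
      pms[[length(pms) + 1]] <- predict_region_mask(model, pt$image)
    }
    pooled_segmentation_metrics(tms, pms)$overall$dsc
  }
}))

`%||%` <- function(a, b) if (is.null(a)) b else a
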