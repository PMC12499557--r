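ns <- asNamespace("pdl1tps")

test_that("selfonn_map at Q=1 is a plain convolution", {
  set.seed(21)
  for (k in 1:20) {
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    x <- array(rnorm(10 * 10 * cin), c(10, 10, cin))
    W <- list(array(rnorm(9 * cin * cout), c(3, 3, cin, cout)))
    y1 <- selfonn_map(x, W, q_order = 1)
    p <- ns$nn_conv_init(cin, cout, 3)
    p$W <- ns$weight_to_mat(W[[1]]); p$b <- numeric(cout)
    y2 <- ns$conv_fwd(p, x)$y
    expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-5)
  }
})

test_that("selfonn_map matches the direct Taylor summation", {
  # scalar case: 0.5 + 2*0.25 + 3*0.125 = 1.375
  x <- array(0.5, c(1, 1, 1))
  W <- lapply(1:3, function(q) array(q, c(1, 1, 1, 1)))
  expect_equal(as.numeric(selfonn_map(x, W, 3)), 1.375)
  # zero input returns the bias alone, any Q
  xz <- array(0, c(6, 6, 2))
  Wz <- lapply(1:4, function(q) array(rnorm(9 * 2 * 3), c(3, 3, 2, 3)))
  b <- rnorm(3)
  y <- selfonn_map(xz, Wz, 4, bias = b)
  for (k in 1:3) expect_equal(unique(as.vector(y[, , k])), b[k])
  expect_error(selfonn_map(xz, Wz, 0), "q_order")
  expect_error(selfonn_map(xz, Wz[1:2], 4), "kernel")
})

test_that("selfonn gradients agree with finite differences", {
  set.seed(22)
  p <- ns$nn_selfonn_init(2, 2, 3, q = 3)
  x <- array(rnorm(8 * 8 * 2) * 0.5, c(8, 8, 2))
  fw <- ns$selfonn_fwd(p, x)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- ns$selfonn_bwd(p, fw, dy)
  eps <- 1e-5
  for (nm in c("W1", "W2", "W3")) {
    for (i in sample(length(p[[nm]]), 5)) {
      p2 <- p; p2[[nm]][i] <- p[[nm]][i] + eps
      fp <- sum(ns$selfonn_fwd(p2, x)$y * dy)
      p2[[nm]][i] <- p[[nm]][i] - eps
      fm <- sum(ns$selfonn_fwd(p2, x)$y * dy)
      expect_lt(abs((fp - fm) / (2 * eps) - bw$grads[[nm]][i]), 1e-3)
    }
  }
  for (i in sample(length(x), 8)) {
    x2 <- x; x2[i] <- x[i] + eps
    fp <- sum(ns$selfonn_fwd(p, x2)$y * dy)
    x2[i] <- x[i] - eps
    fm <- sum(ns$selfonn_fwd(p, x2)$y * dy)
    expect_lt(abs((fp - fm) / (2 * eps) - bw$dx[i]), 1e-3)
  }
})

test_that("segmentation models meet their shape and simplex contracts", {
  set.seed(23)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  for (arch in c("unet", "unet_encoder", "deeplabv3plus",
                 "deeplabv3plus_selfonn")) {
    m <- build_segmentation_model(arch, input_size = 64, base = 4,
                                  seed = 5)
    fw <- ns$seg_forward(m, x)
    expect_equal(dim(fw$prob), c(64, 64, 3))
    expect_equal(apply(fw$prob, c(1, 2), sum),
                 matrix(1, 64, 64), tolerance = 1e-9)
  }
  expect_error(build_segmentation_model("resnet_fpn"))
  expect_error(build_segmentation_model("unet_encoder",
                                        encoder = "efficientnet"),
               "small")
  expect_error(build_classifier("vit"), "small_cnn")
})

test_that("Self-ONN DeepLabV3+ with Q=1 reproduces the conv DeepLabV3+", {
  set.seed(24)
  mc <- build_segmentation_model("deeplabv3plus", input_size = 64,
                                 base = 4, seed = 7)
  mo <- build_segmentation_model("deeplabv3plus_selfonn", input_size = 64,
                                 base = 4, q_order = 1, seed = 8)
  mo <- share_weights_q1(mc, mo)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_equal(ns$seg_forward(mo, x)$logits, ns$seg_forward(mc, x)$logits,
               tolerance = 1e-12)
})

test_that("patch classification is deterministic with valid probabilities", {
  m <- build_classifier(input_size = 32, base = 4, seed = 3)
  img <- array(runif(128 * 128 * 3, 0, 255), c(128, 128, 3))
  p1 <- predict_patch_class(m, img)
  p2 <- predict_patch_class(m, img)
  expect_identical(p1, p2)
  expect_true(p1$prob >= 0.5 && p1$prob <= 1)
  expect_true(p1$label %in% c("tumor", "non-tumor"))
  expect_error(predict_patch_class(m, matrix(0, 10, 10)), "3 channels")
})

test_that("region mask upsampling is block-constant and class-preserving", {
  m <- build_segmentation_model("unet", input_size = 64, base = 4,
                                seed = 9)
  img <- array(runif(128 * 128 * 3, 0, 255), c(128, 128, 3))
  mask <- predict_region_mask(m, img)
  expect_equal(dim(mask), c(128, 128))
  expect_true(all(mask %in% 0:2))
  # nearest-neighbor blocks: every 2x2 block constant
  expect_true(all(mask[seq(1, 127, 2), ] == mask[seq(2, 128, 2), ]))
  # class histogram preserved under integer-factor upsampling
  x <- ns$resize_arr(img / 255, 64)
  am <- apply(ns$seg_forward(m, x)$prob, c(1, 2), which.max) - 1L
  expect_equal(tabulate(mask + 1L, 3) / (128 * 128),
               tabulate(am + 1L, 3) / (64 * 64), tolerance = 1e-12)
})

test_that("training records history, keeps checkpoints, and guards splits", {
  s <- fixture_cohort(4)
  recs <- do.call(rbind, lapply(s, function(x)
    tile_slide(x$image, x$region_mask, 128, min_tumor_pixels = 400,
               slide_id = x$slide_id)))
  folds <- assign_folds(vapply(s, `[[`, character(1), "slide_id"), 2,
                        seed = 3)
  man <- build_manifests(recs, folds)
  m <- build_classifier(input_size = 32, base = 4, seed = 1)
  fit <- suppressWarnings(train_model(m, man$classification, fold = 1,
                                      hyper = list(epochs = 1, lr = 1e-3,
                                                   seed = 2)))
  expect_equal(nrow(fit$history), 1)
  expect_s3_class(fit$model, "cls_model")
  bad <- man$classification
  bad$fold <- 1
  expect_error(suppressWarnings(train_model(m, bad, fold = 1)), "empty")
})

test_that("a segmentation model memorizes a single patch in 20 steps", {
  s <- fixture_cohort(4)[[2]]
  tiles <- tile_slide(s$image, s$region_mask, 128, slide_id = s$slide_id)
  i <- which(tiles$cls_label == "tumor")[1]
  x <- ns$resize_arr(tiles$image[[i]] / 255, 64)
  tm <- matrix(as.integer(round(ns$resize_arr(tiles$mask[[i]], 64,
                                              nearest = TRUE))) + 1L,
               64, 64)
  m <- build_segmentation_model("deeplabv3plus_selfonn", input_size = 64,
                                base = 8, seed = 4)
  st <- ns$adam_init(m$params)
  losses <- numeric(20)
  for (it in 1:20) {
    fw <- ns$seg_forward(m, x)
    ls <- ns$softmax_ce(fw$logits, tm)
    sd <- ns$soft_dice(fw$prob, tm, classes = 2:3)
    losses[it] <- ls$loss + sd$loss
    g <- ns$seg_backward(m, fw$cache, ls$dlogits + sd$dlogits)
    up <- ns$adam_step(m$params, g, st, lr = 1e-2)
    m$params <- up$params; st <- up$state
  }
  expect_lt(losses[20], losses[1])
  am <- apply(ns$seg_forward(m, x)$prob, c(1, 2), which.max)
  expect_gt(mean(am == tm), 0.95)
})

test_that("the detector memorizes one nucleus within two pixels", {
  # single rendered nucleus; 50 optimisation steps must move the prob
  # argmax to within 2 px of the centroid
  h <- matrix(0.05, 32, 32)
  rr <- (row(h) - 16)^2 / 25 + (col(h) - 17)^2 / 16
  h[rr <= 1] <- 0.8
  img <- forward_stain_render(h, matrix(0, 32, 32))
  x <- nuclei_preprocess(img, blur_sigma = 1)
  inst <- matrix(0L, 32, 32); inst[rr <= 1] <- 1L
  pt <- object_probability_targets(inst)
  geom <- star_geometry(8)
  dt <- star_distance_targets(inst, geom)
  det <- build_detector(geom, base = 4, seed = 6)
  st <- ns$adam_init(det$params)
  for (it in 1:50) {
    fw <- ns$det_forward(det, x)
    bl <- ns$bce_loss(fw$prob, pt)
    dpl <- bl$dprob * fw$prob * (1 - fw$prob)
    resid <- fw$radii - dt
    drad <- array(pt, dim(dt)) * sign(resid) / length(resid)
    g <- ns$det_backward(det, fw$cache, dpl, drad)
    up <- ns$adam_step(det$params, g, st, lr = 1e-2)
    det$params <- up$params; st <- up$state
  }
  fw <- ns$det_forward(det, x)
  peak <- which(fw$prob == max(fw$prob), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((peak[1] - 16)^2 + (peak[2] - 17)^2), 2 + 1e-9)
})

test_that("shuffled training labels destroy validation performance", {
  s <- fixture_cohort(6)
  recs <- do.call(rbind, lapply(s, function(x)
    tile_slide(x$image, x$region_mask, 128, min_tumor_pixels = 400,
               slide_id = x$slide_id)))
  folds <- assign_folds(vapply(s, `[[`, character(1), "slide_id"), 3,
                        seed = 3)
  man <- build_manifests(recs, folds)
  set.seed(44)
  shuffled <- man$classification
  tr <- shuffled$fold != 1
  shuffled$cls_label[tr] <- sample(shuffled$cls_label[tr])
  m <- build_classifier(input_size = 48, base = 6, seed = 1)
  fit <- suppressWarnings(train_model(m, shuffled, fold = 1,
                                      hyper = list(lr = 3e-3, epochs = 3,
                                                   batch = 4, seed = 5)))
  expect_lt(fit$val_metric, 0.7)
})
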