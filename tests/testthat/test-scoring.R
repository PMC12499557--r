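test_that("status assignment follows the region classes", {
  mask <- matrix(0L, 10, 10)
  mask[, 4:6] <- 1L
  mask[, 7:10] <- 2L
  det <- data.frame(row = c(2, 2, 2), col = c(2, 5, 9))
  out <- assign_status(det, mask)
  expect_equal(out$status, c("excluded", "positive", "negative"))
  # all-negative mask: every detection negative
  out2 <- assign_status(det, matrix(2L, 10, 10))
  expect_true(all(out2$status == "negative"))
  expect_error(assign_status(data.frame(row = 99, col = 1), mask),
               "out of mask bounds")
  # empty detections pass through
  expect_equal(nrow(assign_status(det[0, ], mask)), 0)
})

test_that("TPS arithmetic and the undefined-score flag", {
  expect_equal(compute_tps(0, 250), 0)
  expect_equal(compute_tps(50, 50), 50)
  expect_equal(compute_tps(13, 87), 13)
  expect_warning(tps0 <- compute_tps(0, 0), "no viable tumor cells")
  expect_true(is.na(tps0))
  expect_equal(attr(tps0, "flag"), "no viable tumor cells")
})

test_that("clinical categories respect the quoted boundaries", {
  expect_equal(as.character(categorize_tps(c(0.5, 50, 49.5, 0, 1, 99))),
               c("negative", "high", "low", "negative", "low", "high"))
  # fuzz against an interval oracle: right-continuous at 50, left-open
  # at 1, gap [49, 50) resolved as low
  set.seed(91)
  x <- c(runif(20000, 0, 100), 0, 1, 49, 49.999, 50, 100,
         1 - 1e-9, 50 - 1e-9)
  oracle <- ifelse(x < 1, "negative", ifelse(x >= 50, "high", "low"))
  expect_identical(as.character(categorize_tps(x)), oracle)
})

test_that("oracle scoring reproduces the generator TPS exactly", {
  for (s in fixture_cohort(4)) {
    sc <- score_slide(s, oracle = TRUE, patch_size = 128)
    expect_identical(sc$tps, s$true_tps)
    expect_identical(sc$n_positive + sc$n_negative,
                     sum(s$centroids$status %in% c("positive", "negative")))
    expect_equal(as.character(sc$category),
                 as.character(categorize_tps(s$true_tps)))
  }
})

test_that("class-0 detections never alter the oracle score", {
  s <- fixture_cohort(4)[[1]]
  base <- score_slide(s, oracle = TRUE, patch_size = 128)
  # inject extra non-tumor nuclei at background pixels
  s2 <- s
  bg <- which(s$region_mask == 0L, arr.ind = TRUE)
  add <- bg[seq(1, nrow(bg), length.out = 25), ]
  s2$centroids <- rbind(s2$centroids,
                        data.frame(row = add[, 1], col = add[, 2],
                                   status = "non-tumor"))
  with_extra <- score_slide(s2, oracle = TRUE, patch_size = 128)
  expect_identical(with_extra$tps, base$tps)
  expect_gt(with_extra$n_excluded, base$n_excluded)
})

test_that("classification metrics match hand-computed confusion counts", {
  # TP=8 FP=2 FN=1 TN=9 for class "a"
  y_true <- c(rep("a", 9), rep("b", 11))
  y_pred <- c(rep("a", 8), "b", rep("a", 2), rep("b", 9))
  m <- classification_metrics(y_true, y_pred, classes = c("a", "b"))
  a <- m$per_class[m$per_class$class == "a", ]
  expect_equal(a$precision, 0.8)
  expect_equal(a$recall, 8 / 9)
  expect_equal(a$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-12)
  expect_equal(round(a$f1, 4), 0.8421)
  expect_equal(m$accuracy, 17 / 20)
  # perfect predictions: all ones
  p <- classification_metrics(y_true, y_true)
  expect_equal(p$accuracy, 1)
  expect_true(all(p$per_class$f1 == 1))
  # all-one-class predictions: recall 1 for that class, specificity 0
  suppressWarnings(q <- classification_metrics(y_true, rep("a", 20),
                                               classes = c("a", "b")))
  qa <- q$per_class[q$per_class$class == "a", ]
  expect_equal(qa$recall, 1)
  expect_equal(qa$specificity, 0)
  expect_equal(qa$fpr, 1)
  expect_error(classification_metrics(character(0), character(0)))
})

test_that("classification metrics agree with a counting oracle on random vectors", {
  set.seed(55)
  for (k in 1:40) {
    K <- sample(2:4, 1)
    n <- sample(20:60, 1)
    yt <- sample(letters[1:K], n, replace = TRUE)
    yp <- sample(letters[1:K], n, replace = TRUE)
    m <- suppressWarnings(classification_metrics(yt, yp,
                                                 classes = letters[1:K]))
    for (cl in letters[1:K]) {
      TP <- sum(yt == cl & yp == cl)
      FP <- sum(yt != cl & yp == cl)
      FN <- sum(yt == cl & yp != cl)
      TN <- n - TP - FP - FN
      r <- m$per_class[m$per_class$class == cl, ]
      expect_equal(r$precision, if (TP + FP == 0) 0 else TP / (TP + FP))
      expect_equal(r$recall, if (TP + FN == 0) 0 else TP / (TP + FN))
      expect_equal(r$specificity, if (TN + FP == 0) 0 else TN / (TN + FP))
    }
    expect_equal(m$accuracy, mean(yt == yp))
  }
})

test_that("segmentation metrics match set-count oracles", {
  A <- matrix(0L, 4, 4); A[1, 1:4] <- 1L
  B <- matrix(0L, 4, 4); B[1, 3:4] <- 1L; B[2, 1:2] <- 1L
  m <- suppressMessages(segmentation_metrics(A, B))
  expect_equal(m$per_class["positive", "dsc"], 0.5)
  expect_equal(m$per_class["positive", "iou"], 1 / 3)
  # identical masks: everything 1
  s <- fixture_cohort(2)[[1]]
  mi <- suppressMessages(segmentation_metrics(s$region_mask,
                                              s$region_mask))
  expect_equal(mi$overall$dsc, 1)
  expect_equal(mi$overall$iou, 1)
  expect_equal(mi$pixel_accuracy, 1)
  # class absent in both: 1 by convention, with a message
  expect_message(m0 <- segmentation_metrics(matrix(0L, 3, 3),
                                            matrix(0L, 3, 3)),
                 "convention")
  expect_equal(m0$overall$dsc, 1)
  # overall is the unweighted mean of the two tumor classes; the printed
  # per-class values 89.58 and 77.36 average to 83.47
  expect_equal(round((89.58 + 77.36) / 2, 2), 83.47)
})

test_that("random masks agree with an independent pixel-count oracle", {
  set.seed(66)
  for (k in 1:25) {
    A <- matrix(sample(0:2, 100, TRUE), 10)
    B <- matrix(sample(0:2, 100, TRUE), 10)
    m <- suppressMessages(segmentation_metrics(A, B))
    for (cl in 1:2) {
      ia <- sum(A == cl & B == cl)
      r <- m$per_class[cl, ]
      expect_equal(r$dsc, 2 * ia / (sum(A == cl) + sum(B == cl)))
      expect_equal(r$iou, ia / sum(A == cl | B == cl))
    }
    expect_equal(m$pixel_accuracy, mean(A == B))
  }
})

test_that("slide agreement handles exact, collinear and degenerate cases", {
  ag <- slide_agreement(c(0, 30, 80), c(0, 30, 80))
  expect_equal(ag$pearson_r, 1)
  expect_equal(ag$mae, 0)
  expect_true(all(diag(ag$confusion) == 1))
  expect_equal(ag$overall_accuracy, 1)
  # collinear shift: correlation 1, MAE 10 (empty confusion rows warn on
  # their zero-denominator metrics; that is the documented behavior)
  ag2 <- suppressWarnings(slide_agreement(c(20, 30, 40), c(10, 20, 30)))
  expect_equal(ag2$pearson_r, 1)
  expect_equal(ag2$mae, 10)
  # constant predictions: correlation undefined
  suppressWarnings(
    expect_message(ag3 <- slide_agreement(c(5, 5, 5), c(1, 2, 3)),
                   "undefined"))
  expect_true(is.na(ag3$pearson_r))
  expect_error(slide_agreement(5, 5), "at least 2")
})
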