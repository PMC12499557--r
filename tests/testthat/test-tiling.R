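test_that("tiling enumerates a row-major grid with half-open extents", {
  img <- array(runif(3000 * 2000 * 3, 0, 255), c(3000, 2000, 3))
  tiles <- tile_slide(img, patch_size = 1000, stride = 1000,
                      slide_id = "s1")
  expect_equal(nrow(tiles), 6)
  expect_equal(tiles$origin_row, rep(c(0, 1000, 2000), each = 2))
  expect_equal(tiles$origin_col, rep(c(0, 1000), 3))
  expect_true(all(vapply(tiles$image, function(x)
    all(dim(x)[1:2] == c(1000, 1000)), logical(1))))
  # partial edge content (rows 3000+, none here; cols 2000 exact) dropped:
  # a 1050x1010 image yields exactly one tile
  t2 <- tile_slide(array(0, c(1050, 1010, 3)), patch_size = 1000)
  expect_equal(nrow(t2), 1)
  # too-small image: empty result plus warning, not an error
  expect_warning(t0 <- tile_slide(array(0, c(500, 500, 3)),
                                  patch_size = 1000), "smaller")
  expect_equal(nrow(t0), 0)
})

test_that("tiles reproduce the slide content exactly", {
  img <- array(seq_len(400 * 400 * 3) %% 251, c(400, 400, 3))
  tiles <- tile_slide(img, patch_size = 200)
  i <- which(tiles$origin_row == 200 & tiles$origin_col == 0)
  expect_identical(tiles$image[[i]], img[201:400, 1:200, , drop = FALSE])
})

test_that("the any-tumor-pixel labeling rule is exact", {
  img <- array(0, c(3000, 2000, 3))
  mask <- matrix(0L, 3000, 2000)
  tiles <- tile_slide(img, mask, patch_size = 1000)
  expect_true(all(tiles$cls_label == "non-tumor"))
  # one class-2 pixel at (1500, 500): only the tile with origin (1000, 0)
  # becomes tumor
  mask[1500, 500] <- 2L
  tiles <- tile_slide(img, mask, patch_size = 1000)
  lab <- tiles$cls_label[tiles$origin_row == 1000 & tiles$origin_col == 0]
  expect_equal(lab, "tumor")
  expect_equal(sum(tiles$cls_label == "tumor"), 1)
  # configurable threshold relabels sparse tiles
  tiles5 <- tile_slide(img, mask, patch_size = 1000, min_tumor_pixels = 5)
  expect_true(all(tiles5$cls_label == "non-tumor"))
  # label re-derivation from the stored mask crop matches the stored label
  s <- fixture_cohort(2)[[2]]
  tl <- tile_slide(s$image, s$region_mask, 128, slide_id = s$slide_id)
  relab <- vapply(tl$mask, function(m)
    if (sum(m > 0) >= 1) "tumor" else "non-tumor", character(1))
  expect_identical(relab, tl$cls_label)
})

test_that("fold assignment is slide-level, balanced, and reproducible", {
  ids66 <- sprintf("wsi_%02d", 1:66)
  f <- assign_folds(ids66, 5, seed = 7)
  expect_setequal(f$slide_id, ids66)
  expect_equal(sort(as.vector(table(f$fold)), decreasing = TRUE),
               c(14, 13, 13, 13, 13))
  expect_identical(f, assign_folds(ids66, 5, seed = 7))
  # 5 slides in 5 folds: one each
  f5 <- assign_folds(letters[1:5], 5, seed = 1)
  expect_equal(sort(f5$fold), 1:5)
  expect_error(assign_folds(c("a", "a", "b"), 2), "duplicate")
  expect_error(assign_folds(letters[1:3], 5), "exceeds")
  expect_error(assign_folds(letters[1:3], 1), ">= 2")
})

test_that("manifests partition patches and enforce mask presence", {
  s <- fixture_cohort(2)
  recs <- do.call(rbind, lapply(s, function(x)
    tile_slide(x$image, x$region_mask, 128, slide_id = x$slide_id)))
  folds <- assign_folds(vapply(s, `[[`, character(1), "slide_id"), 2,
                        seed = 3)
  man <- build_manifests(recs, folds)
  expect_equal(nrow(man$classification), nrow(recs))
  expect_equal(nrow(man$segmentation),
               sum(recs$cls_label == "tumor"))
  # per-fold counts partition the total
  expect_equal(sum(table(man$classification$fold)), nrow(recs))
  # all patches of a slide share its fold
  agg <- tapply(man$classification$fold, man$classification$slide_id,
                function(x) length(unique(x)))
  expect_true(all(agg == 1))
  # empty input: empty manifests with headers
  man0 <- build_manifests(recs[0, ], folds)
  expect_equal(nrow(man0$classification), 0)
  expect_true("cls_label" %in% names(man0$classification))
  # tumor patch without a mask errors with the offending record named
  bad <- recs
  i <- which(bad$cls_label == "tumor")[1]
  bad$mask[i] <- list(NULL)
  expect_error(build_manifests(bad, folds), "without masks")
})

test_that("patch records survive the PNG round trip", {
  s <- fixture_cohort(2)[[1]]
  recs <- tile_slide(s$image, s$region_mask, 128, slide_id = s$slide_id)
  dir <- withr::local_tempdir()
  out <- write_patches(recs[1:3, ], dir)
  expect_true(all(file.exists(out$image_path)))
  back <- read_slide_image(out$image_path[1], out$mask_path[1])
  expect_equal(back$image, unname(recs$image[[1]]))
  expect_identical(back$region_mask, recs$mask[[1]])
})
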