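test_that("tiling: grid arithmetic, edge discard, losslessness", {
  img <- matrix(sample(0:255, 1280 * 960, TRUE), nrow = 960, ncol = 1280)
  ts <- tileImage(img, "img1", "GG3")
  expect_identical(nThumbnails(ts), 20L)                 # 5 cols x 4 rows
  expect_identical(max(thumbnailMeta(ts)$tile_row), 4L)
  expect_identical(max(thumbnailMeta(ts)$tile_col), 5L)

  ## reassembly reproduces the covered 896 x 1120 sub-image exactly
  expect_identical(untileImage(ts), img[1:896, 1:1120])

  ## exact-fit and too-small images
  one <- tileImage(img[1:224, 1:224], "a", "GG1")
  expect_identical(nThumbnails(one), 1L)
  expect_identical(getThumbnail(one, 1), img[1:224, 1:224])
  expect_identical(nThumbnails(tileImage(img[1:960, 1:223], "b", "GG1")), 0L)
})

test_that("class balancing downsamples to the minimum without inventing data", {
  mk <- function(n, grp, id) {
    px <- array(as.raw(sample(0:255, 224 * 224 * n, TRUE)),
                dim = c(224L, 224L, n))
    new("ThumbnailSet", pixels = px,
        meta = data.frame(image_id = sprintf("%s_%d", id, seq_len(n)),
                          tile_row = 1L, tile_col = 1L, group_id = grp))
  }
  ts <- bindThumbnailSets(list(mk(40, "GG1", "a"), mk(25, "GG2", "b"),
                               mk(60, "GG3", "c"), mk(25, "GG4", "d")))
  bal <- balanceClasses(ts, rng_seed = 1)
  expect_identical(
    as.integer(table(factor(thumbnailMeta(bal)$group_id, levels = GGs))),
    rep(25L, 4))
  ## output is a subset of the input (provenance ids survive)
  expect_true(all(thumbnailMeta(bal)$image_id %in% thumbnailMeta(ts)$image_id))
  ## determinism and no-op on already-balanced input
  expect_identical(thumbnailMeta(balanceClasses(ts, rng_seed = 1)),
                   thumbnailMeta(bal))
  expect_identical(nThumbnails(balanceClasses(bal, rng_seed = 2)), 100L)
  ## empty class errors
  ts3 <- bindThumbnailSets(list(mk(5, "GG1", "x"), mk(5, "GG2", "y"),
                                mk(5, "GG3", "z")))
  expect_error(balanceClasses(ts3, rng_seed = 1), "empty class")
})

test_that("train/validation split is stratified, disjoint and exhaustive", {
  px <- array(as.raw(0L), dim = c(224L, 224L, 400L))
  ts <- new("ThumbnailSet", pixels = px,
            meta = data.frame(image_id = sprintf("i%d", 1:400),
                              tile_row = 1L, tile_col = 1L,
                              group_id = rep(GGs, each = 100)))
  spl <- splitTrainVal(ts, 0.75, rng_seed = 4)
  expect_identical(nThumbnails(spl@train), 300L)
  expect_identical(nThumbnails(spl@validation), 100L)
  expect_true(all(table(thumbnailMeta(spl@train)$group_id) == 75L))
  tr_ids <- thumbnailMeta(spl@train)$image_id
  va_ids <- thumbnailMeta(spl@validation)$image_id
  expect_length(intersect(tr_ids, va_ids), 0)
  expect_setequal(c(tr_ids, va_ids), thumbnailMeta(ts)$image_id)
  expect_error(splitTrainVal(ts, 1.0), "between 0 and 1")
  expect_error(splitTrainVal(ts, 0), "between 0 and 1")
})

test_that("augmentation keeps geometry contracts", {
  thumb <- matrix(sample(0:255, 224 * 224, TRUE), 224, 224)
  ## identity transform is pixel-identical
  expect_identical(bruxmorph:::applyAffine(thumb), thumb)
  ## mirrors are involutions
  m1 <- bruxmorph:::applyAffine(thumb, mirror_h = TRUE)
  expect_identical(bruxmorph:::applyAffine(m1, mirror_h = TRUE), thumb)
  m2 <- bruxmorph:::applyAffine(thumb, mirror_v = TRUE)
  expect_identical(bruxmorph:::applyAffine(m2, mirror_v = TRUE), thumb)
  ## any random draw keeps the 224 x 224 frame
  out <- augmentThumbnail(thumb, augmentationConfig(), rng_seed = 9)
  expect_identical(dim(out), c(224L, 224L))
  expect_true(all(out >= 0 & out <= 255))
  ## identity-range config reproduces the input through the random path
  id_cfg <- augmentationConfig(rotation_range = c(0, 0), mirror_h = FALSE,
                               mirror_v = FALSE, translation_range = c(0, 0))
  expect_identical(augmentThumbnail(thumb, id_cfg, rng_seed = 1), thumb)
  ## pure translation moves content where expected
  sh <- bruxmorph:::applyAffine(thumb, tx = 10, ty = 0, fill = 0)
  expect_identical(sh[, 11:224], thumb[, 1:214])
})
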