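## small in-code thumbnail sets keep these tests fast: the full synthetic
## micrograph pipeline is exercised end to end in test-acceptance.R

makeThumbs <- function(n_per_class, maker, seed = 1) {
  set.seed(seed)
  px <- array(raw(0), dim = c(224L, 224L, 4L * n_per_class))
  grp <- rep(GGs, each = n_per_class)
  for (i in seq_len(4L * n_per_class))
    px[, , i] <- as.raw(pmin(pmax(round(maker(grp[i])), 0), 255))
  new("ThumbnailSet", pixels = px,
      meta = data.frame(image_id = sprintf("t%03d", seq_along(grp)),
                        tile_row = 1L, tile_col = 1L, group_id = grp))
}

## tiles whose mean gray level encodes the class
gradedTile <- function(grp) {
  base <- c(GG1 = 60, GG2 = 120, GG3 = 180, GG4 = 230)[[grp]]
  matrix(base + rnorm(224 * 224, 0, 8), 224, 224)
}

test_that("untrained model sits at chance; probabilities normalise", {
  model <- buildClassifier(classifierConfig(epochs = 2L, rng_seed = 1))
  expect_false(model@trained)
  ts <- makeThumbs(10, gradedTile)
  pred <- predictThumbnails(model, ts)
  probs <- as.matrix(pred[, paste0("p_", GGs)])
  expect_identical(ncol(probs), 4L)                    # 4 output categories
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  ## untrained features carry no label information: chance on a balanced set
  acc <- mean(pred$label == thumbnailMeta(ts)$group_id)
  expect_lt(abs(acc - 0.25), 0.05)
})

test_that("the pretrained transfer-learning path reports its unavailability", {
  expect_error(buildClassifier(classifierConfig(backbone = "pretrained_backbone")),
               "pretrained")
  ## but its freeze / head-boost scheme is expressed as LR multipliers
  cfg <- classifierConfig()
  cfg@backbone <- "pretrained_backbone"   # bypass the constructor guard
  model <- buildClassifier(classifierConfig(rng_seed = 1))
  model@config <- cfg
  mult <- layerLRMultipliers(model)
  expect_identical(unname(mult[c("conv1", "conv4", "head")]), c(0, 0, 5))
  expect_true(all(layerLRMultipliers(
    buildClassifier(classifierConfig(rng_seed = 1))) == 1))
})

test_that("training learns an easy contrast task and keeps its contracts", {
  ts <- makeThumbs(20, gradedTile, seed = 2)
  spl <- splitTrainVal(ts, 0.75, rng_seed = 3)
  cfg <- classifierConfig(epochs = 3L, batch_size = 16L, rng_seed = 4)
  fit <- trainClassifier(buildClassifier(cfg), spl)
  h <- modelHistory(fit)
  expect_identical(nrow(h), 3L)                        # history length = epochs
  expect_true(all(diff(h$train_loss) < 0.5))           # loss broadly decreasing
  expect_gt(h$val_accuracy[3], 0.9)                    # trivially separable
  ## determinism: same config and seeds reproduce the same history
  fit2 <- trainClassifier(buildClassifier(cfg), spl)
  expect_equal(modelHistory(fit2), h)
  ## empty training class errors
  sub <- subsetThumbnails(spl@train,
                          which(thumbnailMeta(spl@train)$group_id != "GG2"))
  spl_bad <- new("DatasetSplit", train = sub, validation = spl@validation,
                 fraction = 0.75)
  expect_error(trainClassifier(buildClassifier(cfg), spl_bad), "empty class")
})

test_that("identical images under different labels sit at coin-flip accuracy", {
  ## GG1/GG2 share one appearance, GG3/GG4 another: within each pair the
  ## labels are unlearnable, so validation accuracy approaches 1/2
  pairTile <- function(grp)
    matrix(c(GG1 = 70, GG2 = 70, GG3 = 200, GG4 = 200)[[grp]] +
             rnorm(224 * 224, 0, 5), 224, 224)
  ts <- makeThumbs(16, pairTile, seed = 5)
  spl <- splitTrainVal(ts, 0.75, rng_seed = 6)
  fit <- trainClassifier(buildClassifier(
    classifierConfig(epochs = 3L, batch_size = 16L, rng_seed = 7)), spl)
  acc <- modelHistory(fit)$val_accuracy[3]
  expect_lt(abs(acc - 0.5), 0.2)
})

test_that("training is equivariant under permutation of class labels", {
  ## permuting the class labels of the training data, together with the
  ## matching columns of the initial softmax head, permutes every
  ## prediction identically (all other randomness held fixed)
  ts <- makeThumbs(12, gradedTile, seed = 8)
  perm <- c(GG1 = "GG3", GG2 = "GG1", GG3 = "GG4", GG4 = "GG2")
  pidx <- match(GGs, perm[GGs])   # column of p2 holding class g of p1
  ts_perm <- ts
  ts_perm@meta$group_id <- unname(perm[ts@meta$group_id])
  cfg <- classifierConfig(epochs = 2L, batch_size = 16L, rng_seed = 9)
  spl <- splitTrainVal(ts, 0.75, rng_seed = 10)
  spl_perm <- splitTrainVal(ts_perm, 0.75, rng_seed = 10)
  model <- buildClassifier(cfg)
  ## permute the initial head columns so class c of model_perm starts as
  ## class perm^{-1}(c) of model
  model_perm <- model
  model_perm@weights$W5 <- model@weights$W5[, pidx]
  model_perm@weights$b5 <- model@weights$b5[pidx]
  fit <- trainClassifier(model, spl)
  fit_perm <- trainClassifier(model_perm, spl_perm)
  probe <- makeThumbs(3, gradedTile, seed = 11)
  p1 <- predictThumbnails(fit, probe)
  p2 <- predictThumbnails(fit_perm, probe)
  ## probability columns permute exactly with the labels
  for (g in GGs)
    expect_equal(p2[[paste0("p_", perm[[g]])]], p1[[paste0("p_", g)]],
                 tolerance = 1e-10)
  expect_identical(unname(perm[p1$label]), p2$label)
})

test_that("image-level majority vote follows the stated tie rule", {
  mk_pred <- function(labels, probs) {
    d <- data.frame(image_id = "im", tile_row = 1L, tile_col = 1L,
                    group_id = "unknown", label = labels)
    for (g in GGs) d[[paste0("p_", g)]] <- probs[, g]
    d
  }
  ## unanimous vote
  pr <- matrix(0.05, 20, 4, dimnames = list(NULL, GGs))
  pr[, "GG4"] <- 0.85
  v <- tallyVotes(mk_pred(rep("GG4", 20), pr))
  expect_identical(v$votes, c(GG1 = 0L, GG2 = 0L, GG3 = 0L, GG4 = 20L))
  expect_identical(v$assigned, "GG4")
  expect_false(v$tie)

  ## simple majority 11 vs 9
  lab <- c(rep("GG1", 11), rep("GG2", 9))
  pr2 <- matrix(0.25, 20, 4, dimnames = list(NULL, GGs))
  v2 <- tallyVotes(mk_pred(lab, pr2))
  expect_identical(v2$assigned, "GG1")
  expect_false(v2$tie)

  ## 10-10 tie broken by summed probability, and flagged
  lab3 <- c(rep("GG1", 10), rep("GG2", 10))
  pr3 <- matrix(0.01, 20, 4, dimnames = list(NULL, GGs))
  pr3[1:10, "GG1"] <- 0.91   # sum 9.1
  pr3[11:20, "GG2"] <- 0.87  # sum 8.7
  v3 <- tallyVotes(mk_pred(lab3, pr3))
  expect_identical(v3$assigned, "GG1")
  expect_true(v3$tie)

  ## vote conservation over a real tiled image
  model <- buildClassifier(classifierConfig(epochs = 2L, rng_seed = 12))
  img <- matrix(sample(0:255, 960 * 1280, TRUE), 960, 1280)
  p <- predictImage(model, img, "big")
  expect_identical(sum(p$votes), 20L)
  expect_error(predictImage(model, img[1:100, 1:100], "small"), "smaller")
})
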