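test_that("confusion matrix accumulates (truth, prediction) pairs", {
  ## perfect predictions: all mass on the diagonal
  truth <- rep(GGs, each = 25)
  cm <- confusionMatrix(truth, truth)
  expect_identical(sum(diag(cm)), 100L)
  expect_identical(sum(cm) - sum(diag(cm)), 0L)

  ## empty input gives the all-zero matrix
  cm0 <- confusionMatrix(character(), character())
  expect_true(all(cm0 == 0L))

  ## hand-built 8-item case vs a brute-force tally
  tr <- c("GG1", "GG1", "GG2", "GG3", "GG3", "GG3", "GG4", "GG4")
  pr <- c("GG1", "GG2", "GG2", "GG3", "GG1", "GG3", "GG4", "GG3")
  cm8 <- confusionMatrix(tr, pr)
  brute <- matrix(0L, 4, 4, dimnames = list(truth = GGs, predicted = GGs))
  for (i in seq_along(tr)) brute[tr[i], pr[i]] <- brute[tr[i], pr[i]] + 1L
  expect_identical(cm8, brute)

  ## row sums equal per-class truth counts
  expect_identical(unname(rowSums(cm8)),
                   as.numeric(table(factor(tr, levels = GGs))))

  expect_error(confusionMatrix("GG9", "GG1"), "unknown label")
  expect_error(confusionMatrix(c("GG1", "GG2"), "GG1"), "equal length")
})

test_that("metric panel matches hand-computed one-vs-rest values", {
  ## perfect classifier
  perfect <- diag(c(10L, 20L, 30L, 40L))
  dimnames(perfect) <- list(truth = GGs, predicted = GGs)
  r <- computeMetrics(perfect)
  expect_equal(r@accuracy, 1)
  expect_equal(r@error, 0)
  expect_true(all(r@per_class$fpr == 0))
  expect_true(all(r@per_class$f1 == 1))

  ## 2-class toy matrix [[8,2],[3,7]] embedded in the 4x4 frame
  cm <- matrix(0L, 4, 4, dimnames = list(truth = GGs, predicted = GGs))
  cm[1, 1] <- 8L; cm[1, 2] <- 2L; cm[2, 1] <- 3L; cm[2, 2] <- 7L
  suppressWarnings(r2 <- computeMetrics(cm))
  expect_equal(r2@accuracy, 15 / 20)
  pc <- r2@per_class
  expect_equal(pc$sensitivity[1], 8 / 10)        # TP 8, FN 2
  expect_equal(pc$precision[1], 8 / 11)          # FP 3
  expect_equal(pc$specificity[1], 7 / 10)        # TN 7, FP 3
  expect_equal(pc$fpr[1], 3 / 10)
  expect_equal(pc$f1[1], 2 * (8/11) * (8/10) / ((8/11) + (8/10)))
  expect_equal(pc$sensitivity[2], 7 / 10)
  ## empty classes give NA metrics, flagged by a warning, excluded from macro
  expect_warning(computeMetrics(cm), "undefined")
  expect_true(all(is.na(pc$sensitivity[3:4])))
  expect_equal(r2@macro[["sensitivity"]], mean(c(8/10, 7/10)))

  expect_error(computeMetrics(matrix(0L, 4, 4)), "empty")
})

test_that("specificity + FPR = 1 for every class on arbitrary matrices", {
  set.seed(10)
  for (rep in 1:20) {
    cm <- matrix(rpois(16, 10) + 1L, 4, 4,
                 dimnames = list(truth = GGs, predicted = GGs))
    r <- computeMetrics(cm)
    expect_equal(r@per_class$specificity + r@per_class$fpr, rep(1, 4))
    expect_equal(r@error, 1 - r@accuracy)
    expect_true(all(r@per_class$sensitivity >= 0 & r@per_class$sensitivity <= 1))
  }
})

test_that("metrics are invariant under simultaneous class permutation", {
  set.seed(11)
  cm <- matrix(rpois(16, 8) + 1L, 4, 4, dimnames = list(truth = GGs, predicted = GGs))
  p <- c(3, 1, 4, 2)
  cmp <- cm[p, p]; dimnames(cmp) <- list(truth = GGs, predicted = GGs)
  a <- computeMetrics(cm); b <- computeMetrics(cmp)
  expect_equal(a@accuracy, b@accuracy)
  expect_equal(sort(a@per_class$f1), sort(b@per_class$f1))
  expect_equal(a@macro, b@macro)
})

test_that("image-level accuracy measures the voted assignment", {
  truth <- data.frame(image_id = sprintf("im%d", 1:10),
                      group_id = rep(GGs, length.out = 10))
  pred <- data.frame(image_id = truth$image_id, assigned = truth$group_id)
  expect_equal(imageLevelAccuracy(truth, pred)$accuracy, 1)

  pred2 <- pred
  pred2$assigned[1:5] <- rev(GGs)[match(pred$assigned[1:5], GGs)]  # derange half
  r <- imageLevelAccuracy(truth, pred2)
  expect_equal(r$accuracy, 0.5)
  expect_identical(sum(r$per_group$n), 10L)

  expect_error(imageLevelAccuracy(truth, pred[-1, ]), "im1")
})
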