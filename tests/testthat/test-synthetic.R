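test_that("group defaults encode the four morphology classes", {
  gps <- defaultGroupParams()
  expect_named(gps, GGs)
  expect_equal(vapply(gps, function(g) g@mean_lw, numeric(1)),
               c(GG1 = 1.50, GG2 = 1.72, GG3 = 1.84, GG4 = 1.50))
  expect_equal(vapply(gps, function(g) g@mean_area, numeric(1)),
               c(GG1 = 13.9, GG2 = 11.5, GG3 = 16.9, GG4 = 18.5))
  ## aggregates are a GG4 trait, rare elsewhere
  expect_equal(gps$GG4@p_aggregate, 0.5)
  expect_true(all(vapply(gps[1:3], function(g) g@p_aggregate, numeric(1)) < 0.1))
  expect_error(groupMorphParams("GG1", mean_lw = 0.8), "mean_lw")
  expect_error(groupMorphParams("GG1", p_bud = 1.5), "p_bud")
})

test_that("isolate sampling: zero-variance exactness, determinism, unbiasedness", {
  gp0 <- groupMorphParams("GG3", isolate_sd_lw = 0, isolate_sd_area = 0)
  iso <- sampleIsolateParams(gp0, "x", rng_seed = 42)
  expect_identical(iso@mean_lw, 1.84)
  expect_identical(iso@mean_area, 16.9)

  gp <- groupMorphParams("GG1")
  a <- sampleIsolateParams(gp, "a", rng_seed = 99)
  b <- sampleIsolateParams(gp, "a", rng_seed = 99)
  expect_identical(a@mean_lw, b@mean_lw)
  expect_identical(a@mean_area, b@mean_area)

  ## Monte-Carlo: grand mean of isolate means within 3 SE of the group mean
  n <- 400L
  draws <- vapply(seq_len(n), function(s)
    sampleIsolateParams(gp, "i", rng_seed = 1000L + s)@mean_lw, numeric(1))
  se <- gp@isolate_sd_lw / sqrt(n)
  expect_lt(abs(mean(draws) - 1.50), 3 * se + 1e-3)
})

test_that("cell sampling: sizes, zero-variance closure, aggregates, buds", {
  cfg <- renderConfig()
  expect_identical(nrow(sampleCells(
    sampleIsolateParams(groupMorphParams("GG1"), rng_seed = 1), 0, cfg)), 0L)

  ## zero cell-level CV: every non-bud cell carries the isolate means exactly
  gp0 <- groupMorphParams("GG3", isolate_sd_lw = 0, isolate_sd_area = 0,
                          cell_cv_lw = 0, cell_cv_area = 0)
  iso0 <- sampleIsolateParams(gp0, "z", rng_seed = 5)
  cells0 <- sampleCells(iso0, 40, cfg, rng_seed = 6)
  nb <- cells0[!cells0$is_bud, ]
  expect_equal(nb$true_lw, rep(1.84, nrow(nb)))
  expect_equal(nb$true_area, rep(16.9, nrow(nb)))
  ## geometric consistency: true_lw = a/b and true_area = pi a b c^2
  expect_equal(cells0$true_lw, cells0$a_px / cells0$b_px)
  expect_equal(cells0$true_area,
               pi * cells0$a_px * cells0$b_px * cfg@calibration^2)

  ## aggregate fraction tracks p_aggregate for a GG4 isolate
  iso4 <- sampleIsolateParams(groupMorphParams("GG4"), "g4", rng_seed = 7)
  cells4 <- sampleCells(iso4, 500, cfg, rng_seed = 8)
  mothers <- cells4[!cells4$is_bud, ]
  expect_equal(nrow(mothers), 500L)
  frac <- mean(!is.na(mothers$aggregate_id))
  expect_lt(abs(frac - iso4@p_aggregate), 0.05)
  ## every aggregate has at least 2 members
  agg_sizes <- table(mothers$aggregate_id)
  expect_true(all(agg_sizes >= 2))

  ## buds are smaller than 40% of a typical mother and flagged
  buds <- cells4[cells4$is_bud, ]
  expect_gt(nrow(buds), 0)
  expect_true(all(buds$true_area < 0.4 * max(mothers$true_area)))

  ## determinism
  c1 <- sampleCells(iso4, 50, cfg, rng_seed = 11)
  c2 <- sampleCells(iso4, 50, cfg, rng_seed = 11)
  expect_identical(c1, c2)
})

test_that("cells never overlap outside aggregates and stay inside the field", {
  cfg <- renderConfig()
  iso <- sampleIsolateParams(groupMorphParams("GG4"), "ov", rng_seed = 21)
  cells <- sampleCells(iso, 200, cfg, rng_seed = 22)
  expect_true(all(cells$center_x - cells$a_px >= 0))
  expect_true(all(cells$center_x + cells$a_px <= cfg@width + 1))
  expect_true(all(cells$center_y - cells$a_px >= 0))
  expect_true(all(cells$center_y + cells$a_px <= cfg@height + 1))
  singles <- cells[!cells$is_bud & is.na(cells$aggregate_id), ]
  d <- as.matrix(dist(singles[, c("center_x", "center_y")]))
  rsum <- outer(singles$b_px, singles$b_px, "+")  # conservative inner radii
  diag(d) <- Inf
  expect_true(all(d > rsum - 1e-9))
})

test_that("placement capacity errors are informative", {
  cfg <- renderConfig(width = 230L, height = 230L)
  iso <- sampleIsolateParams(groupMorphParams("GG4"), "full", rng_seed = 1)
  expect_error(sampleCells(iso, 5000, cfg, rng_seed = 2, max_attempts = 50L),
               "could not place")
})

test_that("rendering: background, dimensions, circle area, determinism", {
  cfg <- smallRender(seed = 3)
  empty <- renderField(data.frame(), cfg)
  expect_identical(dim(empty), c(300L, 320L))
  expect_lt(abs(mean(empty) - cfg@background_level), 2)

  kc <- renderKnownCircle(r = 10, noise_sd = 0)
  dark <- sum(kc$img < otsuThreshold(kc$img))
  expect_lt(abs(dark - pi * 100) / (pi * 100), 0.10)

  ## determinism under a fixed render seed
  i1 <- renderField(kc$cells, kc$cfg)
  i2 <- renderField(kc$cells, kc$cfg)
  expect_identical(i1, i2)

  ## cells outside the field are a geometry error
  bad <- kc$cells; bad$center_x <- 2
  expect_error(renderField(bad, kc$cfg), "outside the field")
})
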