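test_that("segmentation finds the rendered cells and nothing in background", {
  cfg <- smallRender()
  blank <- renderField(data.frame(), renderConfig(width = 320L, height = 300L,
                                                  noise_sd = 0, rng_seed = 1))
  expect_identical(nrow(segmentCells(blank)$components), 0L)

  ## five disjoint high-contrast cells, no noise -> exactly five components
  cells <- data.frame(
    cell_id = 1:5,
    center_x = c(60, 150, 250, 70, 240), center_y = c(60, 80, 60, 220, 210),
    a_px = 12, b_px = 8, orientation = c(0, 0.5, 1, 1.5, 2), is_bud = FALSE,
    aggregate_id = NA_integer_, isolate_id = "iso", group_id = "GG1",
    true_lw = 1.5, true_area = pi * 12 * 8 * 0.0625, area_px = pi * 96)
  img <- renderField(cells, renderConfig(width = 320L, height = 300L,
                                         noise_sd = 0, rng_seed = 1))
  seg <- segmentCells(img)
  expect_identical(nrow(seg$components), 5L)

  ## rendered circle: component pixel count close to pi r^2
  kc <- renderKnownCircle(r = 10, noise_sd = 0)
  seg1 <- segmentCells(kc$img)
  expect_identical(nrow(seg1$components), 1L)
  expect_lt(abs(seg1$components$n_px - pi * 100) / (pi * 100), 0.10)
})

test_that("moment-based measurement recovers shape and obeys scaling", {
  ## ideal rasterized circle
  g <- expand.grid(x = -15:15, y = -15:15)
  disk <- as.matrix(g[g$x^2 + g$y^2 <= 100, ])
  m <- measureComponent(disk, calibration = 0.25)
  expect_lt(abs(m[["lw_ratio"]] - 1), 0.05)
  expect_lt(abs(m[["area"]] - pi * 100 * 0.0625) / (pi * 100 * 0.0625), 0.10)

  ## ideal rasterized ellipse a = 20, b = 10 -> ratio 2
  g2 <- expand.grid(x = -25:25, y = -25:25)
  ell <- as.matrix(g2[(g2$x / 20)^2 + (g2$y / 10)^2 <= 1, ])
  m2 <- measureComponent(ell, calibration = 0.25)
  expect_lt(abs(m2[["lw_ratio"]] - 2), 0.1)

  ## doubling the calibration quadruples area, leaves the ratio unchanged
  m3 <- measureComponent(ell, calibration = 0.5)
  expect_equal(m3[["area"]], 4 * m2[["area"]])
  expect_equal(m3[["lw_ratio"]], m2[["lw_ratio"]])

  expect_error(measureComponent(disk[1:3, , drop = FALSE]), "fewer than 5")
  line <- cbind(x = 1:20, y = rep(3L, 20))
  expect_error(measureComponent(line), "degenerate")
})

test_that("measurement on rendered ground truth tracks true morphology", {
  ## render one isolate with generous cells and compare segmentation-based
  ## means to the generator's ground truth
  iso <- sampleIsolateParams(groupMorphParams("GG3"), "m1", rng_seed = 31)
  cfg <- renderConfig(rng_seed = 32)
  cells <- sampleCells(iso, 120, cfg, rng_seed = 33)
  rec <- measureSegmentation(segmentCells(renderField(cells, cfg)),
                             cfg@calibration)
  truth <- cells[!cells$is_bud & is.na(cells$aggregate_id), ]
  expect_gt(nrow(rec), 0.6 * nrow(truth))
  expect_lt(abs(mean(rec$lw_ratio) - mean(truth$true_lw)), 0.15)
  expect_lt(abs(mean(rec$area) - mean(truth$true_area)),
            0.15 * mean(truth$true_area))
})

test_that("selectCells is stratified, excludes buds/aggregates, reproducible", {
  co <- groundTruthCohort(n_isolates_per_group = 1L, images = 3L,
                          cells_per_image = 80L, seed = 17L)
  rec <- selectCells(co$cells, n = 100, rng_seed = 5)
  expect_identical(nrow(rec), 4L * 100L)
  expect_true(all(table(rec$isolate_id) == 100L))
  ## stratification: close to 33/33/34 per image
  per_img <- table(rec$isolate_id, rec$image_id)
  expect_true(all(per_img[per_img > 0] %in% 33:34))
  ## no bud or aggregate cell selected
  key <- paste(co$cells$image_id, co$cells$cell_id)
  flagged <- co$cells$is_bud | !is.na(co$cells$aggregate_id)
  expect_false(any(paste(rec$image_id, rec$cell_index) %in% key[flagged]))
  ## determinism
  expect_identical(rec, selectCells(co$cells, n = 100, rng_seed = 5))
  ## shortfall errors
  expect_error(selectCells(co$cells, n = 10000, rng_seed = 1), "eligible")
  all_buds <- co$cells; all_buds$is_bud <- TRUE
  expect_error(selectCells(all_buds, n = 10, rng_seed = 1), "eligible")
})

test_that("summaries: constants, per-isolate means, group ordering", {
  rec <- data.frame(isolate_id = rep(c("a", "b"), each = 5),
                    group_id = rep(c("GG1", "GG2"), each = 5),
                    image_id = "i", cell_index = 1:10,
                    lw_ratio = 1.5, area = 10, source = "ground_truth")
  s <- summarizeIsolates(rec)
  expect_equal(s$mean_lw, c(1.5, 1.5))
  expect_equal(s$mean_area, c(10, 10))
  g <- summarizeGroups(rec)
  expect_equal(g$group_means$mean_lw, c(1.5, 1.5))
  expect_true(all(c("grid", "density") %in% names(g$density_lw)))

  ## ordering property: groups whose simulated mean areas differ by >= 2 um^2
  ## keep that order in measured group means (GG4 > GG1, GG3 > GG2)
  co <- groundTruthCohort(n_isolates_per_group = 3L, images = 3L,
                          cells_per_image = 80L, seed = 23L)
  rec2 <- selectCells(co$cells, n = 100, rng_seed = 9)
  gm <- summarizeGroups(rec2)$group_means
  area <- setNames(gm$mean_area, gm$group_id)
  expect_gt(area[["GG4"]], area[["GG1"]])
  expect_gt(area[["GG3"]], area[["GG2"]])
  lw <- setNames(gm$mean_lw, gm$group_id)
  expect_gt(lw[["GG3"]], lw[["GG1"]])
})
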