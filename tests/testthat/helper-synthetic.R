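# shared fixtures, built in code at test time

GGs <- c("GG1", "GG2", "GG3", "GG4")

smallRender <- function(seed = NA_real_, ...) {
  renderConfig(width = 320L, height = 300L, rng_seed = seed, ...)
}

## a tiny rendered field with known cells
renderKnownCircle <- function(r = 10, noise_sd = 0, blur_sigma = 1) {
  cfg <- renderConfig(width = 320L, height = 300L, noise_sd = noise_sd,
                      blur_sigma = blur_sigma, rng_seed = 1)
  cells <- data.frame(cell_id = 1L, center_x = 160, center_y = 150,
                      a_px = r, b_px = r, orientation = 0, is_bud = FALSE,
                      aggregate_id = NA_integer_, isolate_id = "iso",
                      group_id = "GG1", true_lw = 1,
                      true_area = pi * r^2 * 0.25^2, area_px = pi * r^2)
  list(cells = cells, img = renderField(cells, cfg), cfg = cfg)
}

## ground-truth-only cohort (no rendering): isolates x images of cell tables
groundTruthCohort <- function(n_isolates_per_group = 2L, images = 3L,
                              cells_per_image = 60L, seed = 7L) {
  simulateCohort(isolates_per_group = n_isolates_per_group,
                 images_per_isolate = images,
                 cells_per_image = cells_per_image,
                 rng_seed = seed, render = FALSE)
}
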