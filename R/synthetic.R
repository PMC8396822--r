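## Synthetic micrograph generator: four genetic groups with distinct cell
## morphology (l/w ratio, area), budding, and the GG4-characteristic
## multicellular aggregates, rendered as 8-bit brightfield-like fields.

GROUP_DEFAULTS <- data.frame(
  group_id = GG_LEVELS,
  mean_lw = c(1.50, 1.72, 1.84, 1.50),
  mean_area = c(13.9, 11.5, 16.9, 18.5)
)

#' Construct group-level morphology parameters
#'
#' Defaults encode the four genetic groups of *B. bruxellensis*: round small
#' cells (GG1), elongated small cells (GG2), elongated large cells (GG3) and
#' round large cells forming multicellular aggregates (GG4). Group means
#' default to l/w 1.50/1.72/1.84/1.50 and area 13.9/11.5/16.9/18.5 um^2.
#'
#' @param group_id `"GG1".."GG4"`.
#' @param mean_lw,mean_area group means (default per group, see above).
#' @param isolate_sd_lw,isolate_sd_area between-isolate SDs of the means.
#' @param cell_cv_lw,cell_cv_area within-isolate coefficients of variation.
#' @param p_bud probability a cell carries a bud.
#' @param p_aggregate probability a cell belongs to a multicellular
#'   aggregate; default 0.5 for GG4 and 0.02 for the other groups, which
#'   only rarely form such structures.
#' @param aggregate_size_range cells per aggregate, uniform over this range.
#' @return A [GroupMorphParams-class] object.
#' @examples
#' groupMorphParams("GG3")
#' @export
groupMorphParams <- function(group_id,
                             mean_lw = NULL, mean_area = NULL,
                             isolate_sd_lw = 0.10, isolate_sd_area = 2.0,
                             cell_cv_lw = 0.12, cell_cv_area = 0.20,
                             p_bud = 0.2,
                             p_aggregate = if (identical(group_id, "GG4")) 0.5 else 0.02,
                             aggregate_size_range = c(3L, 8L)) {
  group_id <- match.arg(group_id, GG_LEVELS)
  row <- GROUP_DEFAULTS[GROUP_DEFAULTS$group_id == group_id, ]
  if (is.null(mean_lw)) mean_lw <- row$mean_lw
  if (is.null(mean_area)) mean_area <- row$mean_area
  new("GroupMorphParams", group_id = group_id,
      mean_lw = mean_lw, mean_area = mean_area,
      isolate_sd_lw = isolate_sd_lw, isolate_sd_area = isolate_sd_area,
      cell_cv_lw = cell_cv_lw, cell_cv_area = cell_cv_area,
      p_bud = p_bud, p_aggregate = p_aggregate,
      aggregate_size_range = as.integer(aggregate_size_range))
}

#' @rdname groupMorphParams
#' @return `defaultGroupParams` returns a named list of the four groups.
#' @export
defaultGroupParams <- function() {
  setNames(lapply(GG_LEVELS, groupMorphParams), GG_LEVELS)
}

#' Construct a render configuration
#'
#' @param width,height field size in pixels (default 1280 x 960).
#' @param calibration micrometres per pixel (default 0.25; the imaging
#'   system's true calibration is not public, so absolute pixel sizes are a
#'   package convention recorded in every ground-truth row).
#' @param background_level background gray level (default 200).
#' @param rim_contrast gray-level drop of the cell rim (default 90).
#' @param blur_sigma Gaussian blur sigma in pixels (default 1).
#' @param noise_sd additive Gaussian noise SD in gray levels (default 3).
#' @param rng_seed seed for the render noise; `NA` uses the current stream.
#' @return A [RenderConfig-class] object.
#' @export
renderConfig <- function(width = 1280L, height = 960L, calibration = 0.25,
                         background_level = 200, rim_contrast = 90,
                         blur_sigma = 1, noise_sd = 3, rng_seed = NA_real_) {
  new("RenderConfig", width = as.integer(width), height = as.integer(height),
      calibration = calibration, background_level = background_level,
      rim_contrast = rim_contrast, blur_sigma = blur_sigma,
      noise_sd = noise_sd, rng_seed = as.numeric(rng_seed))
}

#' Draw isolate-level morphology parameters from a group hyperdistribution
#'
#' Isolate mean l/w and mean area are drawn from truncated normal
#' hyperdistributions centred on the group means (truncation at l/w >= 1.05
#' and area >= 2 um^2), emulating the between-isolate clustering seen when
#' per-isolate averages of 100 cells are plotted per genetic group.
#'
#' @param group a [GroupMorphParams-class] object.
#' @param isolate_id label for the new isolate.
#' @param rng_seed integer seed; identical seeds give identical draws.
#' @return An [IsolateMorphParams-class] object.
#' @examples
#' sampleIsolateParams(groupMorphParams("GG3"), "iso1", rng_seed = 1)
#' @export
sampleIsolateParams <- function(group, isolate_id = group@group_id, rng_seed = NULL) {
  stopifnot(is(group, "GroupMorphParams"))
  validObject(group)
  withSeed(rng_seed, {
    mean_lw <- rtruncnorm1(1L, group@mean_lw, group@isolate_sd_lw, lower = 1.05)
    mean_area <- rtruncnorm1(1L, group@mean_area, group@isolate_sd_area, lower = 2)
    new("IsolateMorphParams",
        isolate_id = as.character(isolate_id), group_id = group@group_id,
        mean_lw = mean_lw, mean_area = mean_area,
        cell_cv_lw = group@cell_cv_lw, cell_cv_area = group@cell_cv_area,
        p_bud = group@p_bud, p_aggregate = group@p_aggregate,
        aggregate_size_range = group@aggregate_size_range)
  })
}

## semi-axes in px from area (um^2) and l/w ratio, given calibration c um/px
axesFromAreaLW <- function(area_um2, lw, c) {
  area_px <- area_um2 / c^2
  b <- sqrt(area_px / (pi * lw))
  list(a = b * lw, b = b)
}

#' Sample and place cells of one isolate in a synthetic field
#'
#' Cell areas and l/w ratios are drawn from lognormal distributions whose
#' arithmetic means equal the isolate means (so zero coefficients of
#' variation reproduce the means exactly). Single cells are placed without
#' overlap by rejection sampling; aggregate members are chained tangent to a
#' previously placed member sharing their `aggregate_id`; buds are attached
#' tangent to their mother, flagged `is_bud`, with area below 40% of the
#' mother's, and inherit the mother's aggregate membership.
#'
#' @param params an [IsolateMorphParams-class] object.
#' @param n_cells number of mother (non-bud) cells to draw; buds appear as
#'   additional rows.
#' @param render_cfg a [RenderConfig-class] giving field size & calibration.
#' @param rng_seed integer seed.
#' @param max_attempts rejection-sampling cap per cell (default 1000).
#' @return A data.frame, one row per cell (the ground-truth table):
#'   `cell_id`, `center_x`, `center_y`, `a_px`, `b_px`, `orientation`,
#'   `is_bud`, `aggregate_id` (NA for single cells), `isolate_id`,
#'   `group_id`, `true_lw`, `true_area` (um^2), `area_px`.
#' @examples
#' iso <- sampleIsolateParams(groupMorphParams("GG1"), "iso1", rng_seed = 1)
#' cells <- sampleCells(iso, 20, renderConfig(), rng_seed = 2)
#' @export
sampleCells <- function(params, n_cells, render_cfg = renderConfig(),
                        rng_seed = NULL, max_attempts = 1000L) {
  stopifnot(is(params, "IsolateMorphParams"), is(render_cfg, "RenderConfig"),
            n_cells >= 0)
  validObject(params); validObject(render_cfg)
  n_cells <- as.integer(n_cells)
  cols <- c("cell_id", "center_x", "center_y", "a_px", "b_px", "orientation",
            "is_bud", "aggregate_id", "isolate_id", "group_id",
            "true_lw", "true_area", "area_px")
  if (n_cells == 0L) {
    out <- data.frame(cell_id = integer(), center_x = numeric(),
                      center_y = numeric(), a_px = numeric(), b_px = numeric(),
                      orientation = numeric(), is_bud = logical(),
                      aggregate_id = integer(), isolate_id = character(),
                      group_id = character(), true_lw = numeric(),
                      true_area = numeric(), area_px = numeric())
    return(out[, cols])
  }
  W <- render_cfg@width; H <- render_cfg@height; cal <- render_cfg@calibration

  withSeed(rng_seed, {
    lw <- rlnormMeanCV(n_cells, params@mean_lw, params@cell_cv_lw)
    lw[lw < 1] <- 1
    area <- rlnormMeanCV(n_cells, params@mean_area, params@cell_cv_area)
    ax <- axesFromAreaLW(area, lw, cal)
    theta <- runif(n_cells, 0, pi)

    ## aggregate membership and sizes
    in_agg <- runif(n_cells) < params@p_aggregate
    agg_id <- rep(NA_integer_, n_cells)
    idx <- which(in_agg)
    if (length(idx) == 1L) { in_agg[idx] <- FALSE; idx <- integer() }
    aid <- 0L
    while (length(idx) >= 2L) {
      size <- sample(params@aggregate_size_range[1]:params@aggregate_size_range[2], 1L)
      size <- min(size, length(idx))
      if (length(idx) - size == 1L) size <- length(idx)  # never strand one
      size <- max(size, 2L)
      aid <- aid + 1L
      agg_id[idx[seq_len(size)]] <- aid
      idx <- idx[-seq_len(size)]
    }

    ## placement; bounding radius approximates the ellipse for overlap tests
    cx <- cy <- numeric(n_cells)
    r_bound <- ax$a
    r_touch <- (ax$a + ax$b) / 2
    placed <- logical(n_cells)
    fail <- function(i) stop(sprintf(
      "could not place cell %d of %d in a %d x %d px field after %d attempts",
      i, n_cells, W, H, max_attempts), call. = FALSE)

    overlaps <- function(i, x, y, same_agg_ok) {
      j <- which(placed)
      if (!length(j)) return(FALSE)
      if (same_agg_ok && !is.na(agg_id[i]))
        j <- j[is.na(agg_id[j]) | agg_id[j] != agg_id[i]]
      if (!length(j)) return(FALSE)
      d2 <- (cx[j] - x)^2 + (cy[j] - y)^2
      any(d2 < (r_touch[j] + r_touch[i] + 1)^2)
    }

    order_idx <- order(!is.na(agg_id), agg_id, na.last = FALSE)
    ## place singles first, then aggregates chained member by member
    for (i in order_idx[is.na(agg_id[order_idx])]) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        x <- runif(1, r_bound[i] + 1, W - r_bound[i] - 1)
        y <- runif(1, r_bound[i] + 1, H - r_bound[i] - 1)
        if (!overlaps(i, x, y, same_agg_ok = FALSE)) { ok <- TRUE; break }
      }
      if (!ok) fail(i)
      cx[i] <- x; cy[i] <- y; placed[i] <- TRUE
    }
    if (aid > 0L) for (a in seq_len(aid)) {
      members <- which(!is.na(agg_id) & agg_id == a)
      for (k in seq_along(members)) {
        i <- members[k]
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          if (k == 1L) {
            x <- runif(1, r_bound[i] + 1, W - r_bound[i] - 1)
            y <- runif(1, r_bound[i] + 1, H - r_bound[i] - 1)
          } else {
            anchor <- members[sample.int(k - 1L, 1L)]
            phi <- runif(1, 0, 2 * pi)
            d <- r_touch[anchor] + r_touch[i]
            x <- cx[anchor] + d * cos(phi)
            y <- cy[anchor] + d * sin(phi)
            if (x < r_bound[i] + 1 || x > W - r_bound[i] - 1 ||
                y < r_bound[i] + 1 || y > H - r_bound[i] - 1) next
          }
          if (!overlaps(i, x, y, same_agg_ok = TRUE)) { ok <- TRUE; break }
        }
        if (!ok) fail(i)
        cx[i] <- x; cy[i] <- y; placed[i] <- TRUE
      }
    }

    ## buds: tangent to mother, < 40% of mother's area, roughly round
    has_bud <- runif(n_cells) < params@p_bud
    nb <- sum(has_bud)
    if (nb > 0L) {
      mother <- which(has_bud)
      bud_area <- area[mother] * runif(nb, 0.10, 0.35)
      bud_lw <- runif(nb, 1.0, 1.15)
      bax <- axesFromAreaLW(bud_area, bud_lw, cal)
      phi <- runif(nb, 0, 2 * pi)
      d <- (ax$a[mother] + ax$b[mother]) / 2 + (bax$a + bax$b) / 2
      bx <- cx[mother] + d * cos(phi)
      by <- cy[mother] + d * sin(phi)
      keep <- bx > bax$a + 1 & bx < W - bax$a - 1 & by > bax$a + 1 & by < H - bax$a - 1
      mother <- mother[keep]; nb <- sum(keep)
    }

    df <- data.frame(
      cell_id = seq_len(n_cells),
      center_x = cx, center_y = cy, a_px = ax$a, b_px = ax$b,
      orientation = theta, is_bud = FALSE, aggregate_id = agg_id,
      isolate_id = params@isolate_id, group_id = params@group_id,
      true_lw = lw, true_area = area, area_px = area / cal^2,
      stringsAsFactors = FALSE)
    if (nb > 0L) {
      bdf <- data.frame(
        cell_id = n_cells + seq_len(nb),
        center_x = bx[keep], center_y = by[keep],
        a_px = bax$a[keep], b_px = bax$b[keep],
        orientation = runif(nb, 0, pi), is_bud = TRUE,
        aggregate_id = agg_id[mother],
        isolate_id = params@isolate_id, group_id = params@group_id,
        true_lw = bud_lw[keep], true_area = bud_area[keep],
        area_px = bud_area[keep] / cal^2,
        stringsAsFactors = FALSE)
      df <- rbind(df, bdf)
    }
    df[, cols]
  })
}

#' Render a cell population as an 8-bit grayscale micrograph
#'
#' Brightfield-like render: uniform light background, each cell drawn as a
#' dark elliptical rim with a moderately darker interior, followed by a
#' Gaussian blur and additive Gaussian read noise. Deterministic given
#' `render_cfg@rng_seed`.
#'
#' @param cells ground-truth data.frame from [sampleCells()] (may be empty).
#' @param render_cfg a [RenderConfig-class].
#' @return Integer matrix `height x width` of gray levels 0..255.
#' @examples
#' img <- renderField(sampleCells(
#'   sampleIsolateParams(groupMorphParams("GG2"), rng_seed = 1),
#'   15, renderConfig(), rng_seed = 2), renderConfig(rng_seed = 3))
#' @export
renderField <- function(cells, render_cfg = renderConfig()) {
  stopifnot(is(render_cfg, "RenderConfig"), is.data.frame(cells))
  validObject(render_cfg)
  W <- render_cfg@width; H <- render_cfg@height
  bg <- render_cfg@background_level
  rim <- bg - render_cfg@rim_contrast
  interior <- bg - 0.6 * render_cfg@rim_contrast
  canvas <- matrix(bg, nrow = H, ncol = W)

  if (nrow(cells)) {
    if (any(cells$center_x - cells$a_px < 0 | cells$center_x + cells$a_px > W + 1 |
            cells$center_y - cells$a_px < 0 | cells$center_y + cells$a_px > H + 1))
      stop("cell extends outside the field; regenerate with a larger field",
           call. = FALSE)
    for (i in seq_len(nrow(cells))) {
      a <- cells$a_px[i]; b <- cells$b_px[i]
      x0 <- cells$center_x[i]; y0 <- cells$center_y[i]
      th <- cells$orientation[i]
      xr <- max(1L, floor(x0 - a)):min(W, ceiling(x0 + a))
      yr <- max(1L, floor(y0 - a)):min(H, ceiling(y0 + a))
      dx <- outer(rep(1, length(yr)), xr - x0)
      dy <- outer(yr - y0, rep(1, length(xr)))
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      d <- sqrt(u^2 + v^2)
      tband <- 1.4 / b  # rim half-thickness ~1.4 px in normalized units
      patch <- canvas[yr, xr]
      inside <- d <= 1
      rimmask <- d > 1 - 2 * tband & inside
      patch[inside] <- pmin(patch[inside], interior)
      patch[rimmask] <- pmin(patch[rimmask], rim)
      canvas[yr, xr] <- patch
    }
  }

  if (render_cfg@blur_sigma > 0)
    canvas <- cpp_gaussian_blur(canvas, render_cfg@blur_sigma)
  canvas <- withSeed(if (is.na(render_cfg@rng_seed)) NULL else render_cfg@rng_seed, {
    if (render_cfg@noise_sd > 0)
      canvas + matrix(rnorm(length(canvas), 0, render_cfg@noise_sd), nrow = H)
    else canvas
  })
  matrix(as.integer(round(pmin(pmax(canvas, 0), 255))), nrow = H)
}

#' Simulate a cohort of isolates with rendered images and ground truth
#'
#' Convenience driver: draws isolates from each group's hyperdistribution,
#' renders `images_per_isolate` fields per isolate, and returns the images,
#' the combined ground-truth table and a manifest-style index. Seeds for
#' every isolate and image are derived deterministically from `rng_seed`.
#'
#' @param groups named list of [GroupMorphParams-class] (default all four).
#' @param isolates_per_group,images_per_isolate cohort design.
#' @param cells_per_image mother cells per field (default 280, emulating a
#'   well-grown 72-h culture at x40; about 13 single cells per 224 px tile).
#' @param render_cfg a [RenderConfig-class].
#' @param rng_seed master seed.
#' @param render if `FALSE`, skip rendering and return ground truth only.
#' @return list with `images` (named list of matrices, NULL if
#'   `render = FALSE`), `cells` (ground-truth data.frame with `image_id`),
#'   and `index` (data.frame image_id/isolate_id/group_id).
#' @export
simulateCohort <- function(groups = defaultGroupParams(),
                           isolates_per_group = 2L, images_per_isolate = 10L,
                           cells_per_image = 280L,
                           render_cfg = renderConfig(), rng_seed = 1L,
                           render = TRUE) {
  images <- list(); cells_all <- list(); idx <- list()
  base <- as.integer(rng_seed) %% 100000L
  k <- 0L
  for (g in seq_along(groups)) {
    gp <- groups[[g]]
    for (i in seq_len(isolates_per_group)) {
      iso_id <- sprintf("%s_iso%02d", gp@group_id, i)
      iso <- sampleIsolateParams(gp, iso_id, rng_seed = base + 131L * g + 7L * i)
      for (im in seq_len(images_per_isolate)) {
        k <- k + 1L
        image_id <- sprintf("%s_img%02d", iso_id, im)
        seed_im <- (base + 7919L * k) %% .Machine$integer.max
        cells <- sampleCells(iso, cells_per_image, render_cfg, rng_seed = seed_im)
        cells$image_id <- image_id
        cells_all[[k]] <- cells
        if (render) {
          cfg <- render_cfg; cfg@rng_seed <- as.numeric(seed_im + 1L)
          images[[image_id]] <- renderField(cells, cfg)
        }
        idx[[k]] <- data.frame(image_id = image_id, isolate_id = iso_id,
                               group_id = gp@group_id, stringsAsFactors = FALSE)
      }
    }
  }
  list(images = if (render) images else NULL,
       cells = do.call(rbind, cells_all),
       index = do.call(rbind, idx))
}
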