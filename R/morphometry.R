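## Quantitative morphometry: segment dark cells in a brightfield render,
## measure the length/width ratio and area of each component via the
## second-moment equivalent ellipse, pseudo-randomly select 100 single
## cells per isolate (excluding buds), and summarize per isolate and group.

#' Segment cells in an 8-bit grayscale micrograph
#'
#' Global thresholding (Otsu by default; cells are darker than background)
#' followed by 8-connected component labeling. Components touching the
#' image border or smaller than `min_area_px` are discarded.
#'
#' @param image gray-level matrix.
#' @param threshold gray-level cutoff; pixels strictly below it are
#'   foreground. `NULL` (default) uses [otsuThreshold()].
#' @param min_area_px minimum component size in pixels (default 30, which
#'   rejects noise specks).
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `components`, a data.frame (`label`, `n_px`, `cx`, `cy`) of retained
#'   components. A uniform image yields zero components.
#' @export
segmentCells <- function(image, threshold = NULL, min_area_px = 30L) {
  assertGrayImage(image)
  if (is.null(threshold)) {
    rng <- range(image)
    if (diff(rng) < 1)  # uniform image: nothing to segment
      return(list(labels = matrix(0L, nrow(image), ncol(image)),
                  components = data.frame(label = integer(), n_px = integer(),
                                          cx = numeric(), cy = numeric())))
    threshold <- otsuThreshold(image)
  }
  mask <- image < threshold
  labels <- cpp_label_components(mask)
  nlab <- max(labels)
  if (nlab == 0L)
    return(list(labels = labels,
                components = data.frame(label = integer(), n_px = integer(),
                                        cx = numeric(), cy = numeric())))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  n_px <- tabulate(lab, nbins = nlab)
  border <- rows == 1L | rows == nrow(labels) | cols == 1L | cols == ncol(labels)
  touches <- logical(nlab)
  touches[unique(lab[border])] <- TRUE
  keep <- which(n_px >= min_area_px & !touches)
  comp <- data.frame(
    label = keep,
    n_px = n_px[keep],
    cx = vapply(keep, function(l) mean(cols[lab == l]), numeric(1)),
    cy = vapply(keep, function(l) mean(rows[lab == l]), numeric(1)))
  list(labels = labels, components = comp)
}

#' Measure a labeled component's l/w ratio and area
#'
#' Area is the pixel count times the squared calibration; length and width
#' are the major/minor axis lengths of the ellipse with the same second
#' moments as the pixel set (the "fit ellipse" convention), so the ratio is
#' >= 1 by construction.
#'
#' @param pixels two-column matrix of (x, y) pixel coordinates, or a
#'   segmentation result plus a `label`.
#' @param calibration micrometres per pixel.
#' @return Named numeric: `lw_ratio`, `area` (um^2), `n_px`.
#' @examples
#' disk <- expand.grid(x = -12:12, y = -12:12)
#' disk <- as.matrix(disk[disk$x^2 + disk$y^2 <= 100, ])
#' measureComponent(disk, calibration = 0.25)
#' @export
measureComponent <- function(pixels, calibration = 0.25) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2L)
  n <- nrow(pixels)
  if (n < 5L) stop("component has fewer than 5 pixels", call. = FALSE)
  x <- pixels[, 1]; y <- pixels[, 2]
  mxx0 <- mean((x - mean(x))^2)
  myy0 <- mean((y - mean(y))^2)
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  ## degeneracy is judged on the raw moments (a collinear pixel set has a
  ## zero eigenvalue before the pixel-area correction)
  disc0 <- sqrt(max((mxx0 + myy0)^2 / 4 - (mxx0 * myy0 - mxy^2), 0))
  if ((mxx0 + myy0) / 2 - disc0 <= 1e-9)
    stop("degenerate (collinear) component; cannot fit an ellipse", call. = FALSE)
  ## central second moments with the 1/12 pixel-area correction
  mxx <- mxx0 + 1 / 12
  myy <- myy0 + 1 / 12
  tr <- mxx + myy
  det <- mxx * myy - mxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  c(lw_ratio = sqrt(l1 / l2), area = n * calibration^2, n_px = n)
}

componentPixels <- function(labels, label) {
  idx <- which(labels == label)
  cbind(x = (idx - 1L) %/% nrow(labels) + 1L,
        y = (idx - 1L) %% nrow(labels) + 1L)
}

#' Measure every retained component of a segmentation
#'
#' @param seg result of [segmentCells()].
#' @param calibration micrometres per pixel.
#' @param image_id,isolate_id provenance for the records.
#' @return data.frame of morphometry records with `source = "segmentation"`.
#' @export
measureSegmentation <- function(seg, calibration = 0.25,
                                image_id = NA_character_,
                                isolate_id = NA_character_) {
  comp <- seg$components
  if (!nrow(comp))
    return(data.frame(isolate_id = character(), image_id = character(),
                      cell_index = integer(), lw_ratio = numeric(),
                      area = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  meas <- t(vapply(comp$label, function(l)
    measureComponent(componentPixels(seg$labels, l), calibration),
    numeric(3)))
  data.frame(isolate_id = isolate_id, image_id = image_id,
             cell_index = comp$label,
             lw_ratio = meas[, "lw_ratio"], area = meas[, "area"],
             source = "segmentation", stringsAsFactors = FALSE)
}

#' Pseudo-randomly select n single cells per isolate from ground truth
#'
#' Mirrors the study's measurement protocol: per isolate, 3 images are
#' used and `n` single cells are selected pseudo-randomly, excluding buds
#' (and, by default, aggregate members, whose outlines cannot be measured
#' as single cells). Selection is stratified as evenly as possible across
#' the isolate's selected images (about 33/33/34 for n = 100) and is
#' deterministic given the seed.
#'
#' @param cells ground-truth data.frame from [sampleCells()] /
#'   [simulateCohort()], with an `image_id` column.
#' @param n cells per isolate (default 100).
#' @param rng_seed integer seed.
#' @param exclude_buds,exclude_aggregates eligibility filters (defaults TRUE).
#' @param images_per_isolate number of images drawn on per isolate
#'   (default 3; fewer are used if fewer exist).
#' @return data.frame of morphometry records (`isolate_id`, `group_id`,
#'   `image_id`, `cell_index`, `lw_ratio`, `area`,
#'   `source = "ground_truth"`), exactly `n` rows per isolate.
#' @export
selectCells <- function(cells, n = 100L, rng_seed = NULL,
                        exclude_buds = TRUE, exclude_aggregates = TRUE,
                        images_per_isolate = 3L) {
  stopifnot(is.data.frame(cells), "image_id" %in% names(cells))
  elig <- cells
  if (exclude_buds) elig <- elig[!elig$is_bud, ]
  if (exclude_aggregates) elig <- elig[is.na(elig$aggregate_id), ]
  isolates <- unique(cells$isolate_id)
  withSeed(rng_seed, {
    out <- lapply(isolates, function(iso) {
      sub <- elig[elig$isolate_id == iso, ]
      imgs <- unique(sub$image_id)
      if (length(imgs) > images_per_isolate)
        imgs <- sort(imgs)[seq_len(images_per_isolate)]
      sub <- sub[sub$image_id %in% imgs, ]
      if (nrow(sub) < n)
        stop(sprintf(
          "isolate %s has only %d eligible cells over %d images; %d required",
          iso, nrow(sub), length(imgs), n), call. = FALSE)
      ## even stratification across images, remainder to the later images
      quota <- rep(n %/% length(imgs), length(imgs))
      extra <- n %% length(imgs)
      if (extra) quota[length(imgs) - seq_len(extra) + 1L] <- quota[length(imgs) - seq_len(extra) + 1L] + 1L
      ## rebalance if one image lacks cells
      avail <- vapply(imgs, function(im) sum(sub$image_id == im), integer(1))
      while (any(quota > avail)) {
        over <- which(quota > avail)[1]
        deficit <- quota[over] - avail[over]
        quota[over] <- avail[over]
        room <- which(quota < avail)
        if (!length(room)) stop("internal quota rebalance failed", call. = FALSE)
        quota[room[1]] <- quota[room[1]] + deficit
      }
      picks <- unlist(lapply(seq_along(imgs), function(k) {
        rows <- which(sub$image_id == imgs[k])
        rows[sample.int(length(rows), quota[k])]
      }), use.names = FALSE)
      sel <- sub[picks, ]
      data.frame(isolate_id = iso,
                 group_id = sel$group_id,
                 image_id = sel$image_id,
                 cell_index = sel$cell_id,
                 lw_ratio = sel$true_lw, area = sel$true_area,
                 source = "ground_truth", stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Per-isolate morphometry summaries
#'
#' @param records morphometry records from [selectCells()] or
#'   [measureSegmentation()] (needs `isolate_id`, `lw_ratio`, `area`;
#'   `group_id` is carried through when present).
#' @return data.frame: `isolate_id`, `group_id`, `mean_lw`, `mean_area`,
#'   `n_cells`.
#' @export
summarizeIsolates <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  split_rec <- split(records, records$isolate_id)
  out <- lapply(split_rec, function(r) data.frame(
    isolate_id = r$isolate_id[1],
    group_id = if ("group_id" %in% names(r)) r$group_id[1] else NA_character_,
    mean_lw = mean(r$lw_ratio), mean_area = mean(r$area),
    n_cells = nrow(r), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-group morphometry summaries and density tables
#'
#' Group means are taken over cell-level records; kernel-density tables
#' (512-point grid) are returned per group for both the l/w ratio and the
#' area, mirroring the per-group density-curve presentation of isolate
#' morphology.
#'
#' @param records cell-level morphometry records with `group_id`.
#' @return list with `group_means` (data.frame `group_id`, `mean_lw`,
#'   `mean_area`, `n_cells`), `density_lw` and `density_area` (data.frames
#'   `group_id`, `grid`, `density`).
#' @export
summarizeGroups <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            "group_id" %in% names(records))
  groups <- intersect(GG_LEVELS, unique(records$group_id))
  gm <- do.call(rbind, lapply(groups, function(g) {
    r <- records[records$group_id == g, ]
    data.frame(group_id = g, mean_lw = mean(r$lw_ratio),
               mean_area = mean(r$area), n_cells = nrow(r),
               stringsAsFactors = FALSE)
  }))
  dens <- function(values, g) {
    d <- density(values, n = 512)
    data.frame(group_id = g, grid = d$x, density = d$y,
               stringsAsFactors = FALSE)
  }
  density_lw <- do.call(rbind, lapply(groups, function(g)
    dens(records$lw_ratio[records$group_id == g], g)))
  density_area <- do.call(rbind, lapply(groups, function(g)
    dens(records$area[records$group_id == g], g)))
  list(group_means = gm, density_lw = density_lw, density_area = density_area)
}
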