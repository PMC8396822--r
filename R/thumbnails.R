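## 224 x 224 thumbnail pipeline: non-overlapping top-left tiling, class
## balancing by downsampling to the smallest class, stratified 75/25
## train/validation split, and on-the-fly geometric augmentation.

TILE <- 224L

emptyThumbnailMeta <- function() {
  data.frame(image_id = character(), tile_row = integer(),
             tile_col = integer(), group_id = character(),
             stringsAsFactors = FALSE)
}

newThumbnailSet <- function(pixels, meta) {
  new("ThumbnailSet", pixels = pixels, meta = meta)
}

rawTile <- function(img) as.raw(pmin(pmax(round(img), 0), 255))

#' Cut a micrograph into 224 x 224 thumbnails
#'
#' Non-overlapping grid anchored at the image's top-left corner; partial
#' tiles at the right/bottom edges are discarded; tiles are emitted in
#' row-major order. A 1280 x 960 image yields 5 x 4 = 20 thumbnails.
#'
#' @param image integer/numeric gray-level matrix (rows x cols).
#' @param image_id,group_id provenance recorded on every tile.
#' @param tile_size tile edge in pixels (default 224, the CNN input size).
#' @return A [ThumbnailSet-class]; images smaller than one tile yield an
#'   empty set.
#' @examples
#' ts <- tileImage(matrix(128L, 960, 1280), "img1", "GG1")
#' nThumbnails(ts)  # 20
#' @export
tileImage <- function(image, image_id, group_id, tile_size = TILE) {
  assertGrayImage(image)
  stopifnot(nzchar(image_id), nzchar(group_id))
  nr <- nrow(image) %/% tile_size
  nc <- ncol(image) %/% tile_size
  n <- nr * nc
  if (n == 0L)
    return(newThumbnailSet(array(raw(0), dim = c(TILE, TILE, 0L)),
                           emptyThumbnailMeta()))
  px <- array(raw(0), dim = c(tile_size, tile_size, n))
  meta <- emptyThumbnailMeta()[rep(1L, 0L), ]
  rows <- integer(n); cols <- integer(n)
  k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    k <- k + 1L
    block <- image[((r - 1L) * tile_size + 1L):(r * tile_size),
                   ((cc - 1L) * tile_size + 1L):(cc * tile_size)]
    px[, , k] <- rawTile(block)
    rows[k] <- r; cols[k] <- cc
  }
  newThumbnailSet(px, data.frame(
    image_id = image_id, tile_row = rows, tile_col = cols,
    group_id = group_id, stringsAsFactors = FALSE))
}

#' Combine and subset thumbnail sets
#'
#' @param sets list of [ThumbnailSet-class] objects.
#' @return `bindThumbnailSets` concatenates; `subsetThumbnails` selects
#'   tiles by index keeping provenance.
#' @export
bindThumbnailSets <- function(sets) {
  sets <- Filter(function(s) nThumbnails(s) > 0L, sets)
  if (!length(sets))
    return(newThumbnailSet(array(raw(0), dim = c(TILE, TILE, 0L)),
                           emptyThumbnailMeta()))
  n <- vapply(sets, nThumbnails, integer(1))
  px <- array(raw(0), dim = c(TILE, TILE, sum(n)))
  off <- 0L
  for (s in sets) {
    px[, , off + seq_len(nThumbnails(s))] <- s@pixels
    off <- off + nThumbnails(s)
  }
  newThumbnailSet(px, do.call(rbind, lapply(sets, thumbnailMeta)))
}

#' @rdname bindThumbnailSets
#' @param x a [ThumbnailSet-class].
#' @param i integer index vector.
#' @export
subsetThumbnails <- function(x, i) {
  stopifnot(is(x, "ThumbnailSet"))
  i <- as.integer(i)
  stopifnot(all(i >= 1L & i <= nThumbnails(x)))
  newThumbnailSet(x@pixels[, , i, drop = FALSE],
                  x@meta[i, , drop = FALSE])
}

#' Balance thumbnail classes by downsampling to the smallest class
#'
#' Every class is downsampled without replacement to the minimum class
#' count (in the full training design this is 3000, set by GG4). The output
#' is a subset of the input; selection is deterministic given the seed.
#'
#' @param thumbs a [ThumbnailSet-class] with `group_id` labels.
#' @param rng_seed integer seed.
#' @param classes class labels that must be present (default GG1..GG4).
#' @return A balanced [ThumbnailSet-class].
#' @export
balanceClasses <- function(thumbs, rng_seed = NULL, classes = GG_LEVELS) {
  stopifnot(is(thumbs, "ThumbnailSet"))
  grp <- thumbs@meta$group_id
  counts <- table(factor(grp, levels = classes))
  if (any(counts == 0L))
    stop("cannot balance: empty class(es) ",
         paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
  m <- min(counts)
  keep <- withSeed(rng_seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(grp == cl)
      sort(sample(idx, m))
    }), use.names = FALSE)
  })
  subsetThumbnails(thumbs, keep)
}

#' Stratified train/validation split
#'
#' Random split per class so the validation set stays class-balanced when
#' the input is balanced; default fraction 0.75 for training and 0.25 for
#' validation.
#'
#' @param thumbs a [ThumbnailSet-class].
#' @param fraction per-class training fraction, strictly in (0, 1).
#' @param rng_seed integer seed.
#' @return A [DatasetSplit-class]; train and validation are disjoint and
#'   their union is the input.
#' @export
splitTrainVal <- function(thumbs, fraction = 0.75, rng_seed = NULL) {
  stopifnot(is(thumbs, "ThumbnailSet"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1", call. = FALSE)
  grp <- thumbs@meta$group_id
  train_idx <- withSeed(rng_seed, {
    unlist(lapply(unique(grp), function(cl) {
      idx <- which(grp == cl)
      sort(sample(idx, round(fraction * length(idx))))
    }), use.names = FALSE)
  })
  val_idx <- setdiff(seq_len(nThumbnails(thumbs)), train_idx)
  new("DatasetSplit",
      train = subsetThumbnails(thumbs, sort(train_idx)),
      validation = subsetThumbnails(thumbs, sort(val_idx)),
      fraction = fraction)
}

#' Construct an augmentation configuration
#'
#' @param rotation_range degrees (default c(-45, 45), continuous uniform).
#' @param mirror_h,mirror_v enable horizontal / vertical mirrors.
#' @param translation_range pixels (default c(-30, 30) on both axes).
#' @param fill gray level for exposed pixels; `NA` (default) uses the
#'   thumbnail's median, a robust estimate of its background level.
#' @return An [AugmentationConfig-class].
#' @export
augmentationConfig <- function(rotation_range = c(-45, 45),
                               mirror_h = TRUE, mirror_v = TRUE,
                               translation_range = c(-30, 30),
                               fill = NA_real_) {
  new("AugmentationConfig", rotation_range = as.numeric(rotation_range),
      mirror_h = mirror_h, mirror_v = mirror_v,
      translation_range = as.numeric(translation_range),
      fill = as.numeric(fill))
}

## output-pixel grid, centered, precomputed once
.aug_grid <- local({
  ctr <- (TILE + 1) / 2
  g <- expand.grid(r = seq_len(TILE), c = seq_len(TILE))
  list(r = g$r - ctr, c = g$c - ctr, ctr = ctr)
})

#' Apply one random geometric augmentation to a thumbnail
#'
#' Draws a rotation angle and x/y translation uniformly from the configured
#' ranges and each enabled mirror with probability 1/2, then resamples the
#' thumbnail by nearest-neighbour inverse mapping. Exposed pixels take the
#' fill value. The identity configuration returns the input unchanged.
#'
#' @param thumb 224 x 224 gray-level matrix.
#' @param cfg an [AugmentationConfig-class].
#' @param rng_seed optional integer seed for the parameter draw.
#' @return A 224 x 224 integer matrix.
#' @export
augmentThumbnail <- function(thumb, cfg = augmentationConfig(), rng_seed = NULL) {
  assertGrayImage(thumb)
  stopifnot(is(cfg, "AugmentationConfig"), all(dim(thumb) == TILE))
  withSeed(rng_seed, {
    ang <- runif(1, cfg@rotation_range[1], cfg@rotation_range[2]) * pi / 180
    tx <- runif(1, cfg@translation_range[1], cfg@translation_range[2])
    ty <- runif(1, cfg@translation_range[1], cfg@translation_range[2])
    mh <- cfg@mirror_h && runif(1) < 0.5
    mv <- cfg@mirror_v && runif(1) < 0.5
    applyAffine(thumb, ang, tx, ty, mh, mv, cfg@fill)
  })
}

## deterministic core of the augmentation: rotation (about the center),
## then translation, with optional mirrors; inverse-mapped, nearest neighbor
applyAffine <- function(thumb, angle = 0, tx = 0, ty = 0,
                        mirror_h = FALSE, mirror_v = FALSE, fill = NA_real_) {
  if (angle == 0 && tx == 0 && ty == 0 && !mirror_h && !mirror_v)
    return(matrix(as.integer(round(thumb)), TILE, TILE))
  g <- .aug_grid
  rr <- g$r - ty; cc <- g$c - tx          # undo translation (x = cols, y = rows)
  ca <- cos(-angle); sa <- sin(-angle)    # undo rotation
  rs <- rr * ca - cc * sa
  cs <- rr * sa + cc * ca
  rs <- round(rs + g$ctr); cs <- round(cs + g$ctr)
  if (mirror_h) cs <- TILE + 1 - cs       # horizontal mirror flips columns
  if (mirror_v) rs <- TILE + 1 - rs
  ok <- rs >= 1 & rs <= TILE & cs >= 1 & cs <= TILE
  if (is.na(fill)) fill <- stats::median(thumb)
  out <- rep(as.integer(round(fill)), TILE * TILE)
  out[ok] <- as.integer(round(thumb[cbind(rs[ok], cs[ok])]))
  matrix(out, TILE, TILE)
}

#' Reassemble the covered sub-image from a single image's tiles
#'
#' Inverse of [tileImage()] over the covered region: concatenating the tiles
#' of one image reproduces its top-left `224*nrow x 224*ncol` sub-image
#' exactly.
#'
#' @param thumbs a [ThumbnailSet-class] holding the tiles of one image.
#' @return Integer gray-level matrix.
#' @export
untileImage <- function(thumbs) {
  stopifnot(is(thumbs, "ThumbnailSet"), nThumbnails(thumbs) > 0L)
  meta <- thumbs@meta
  stopifnot(length(unique(meta$image_id)) == 1L)
  nr <- max(meta$tile_row); nc <- max(meta$tile_col)
  out <- matrix(0L, nr * TILE, nc * TILE)
  for (k in seq_len(nThumbnails(thumbs))) {
    r <- meta$tile_row[k]; cc <- meta$tile_col[k]
    out[((r - 1L) * TILE + 1L):(r * TILE),
        ((cc - 1L) * TILE + 1L):(cc * TILE)] <- getThumbnail(thumbs, k)
  }
  out
}
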