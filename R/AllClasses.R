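GG_LEVELS <- c("GG1", "GG2", "GG3", "GG4")

## Central S4 containers. Images themselves stay plain numeric matrices
## (gray levels 0..255, rows = image rows); per-cell ground truth stays a
## data.frame, one row per rendered cell.

#' Group-level morphology parameters
#'
#' Hyperparameters of one genetic group's cell-morphology distribution:
#' target mean length/width ratio and mean single-cell area (micrometres
#' squared), between-isolate standard deviations, within-isolate coefficients
#' of variation, and the budding / aggregation behaviour. Defaults encode the
#' four *Brettanomyces bruxellensis* genetic groups: mean l/w 1.50, 1.72,
#' 1.84, 1.50 and mean area 13.9, 11.5, 16.9, 18.5 um^2 for GG1-GG4, with
#' multicellular aggregates characteristic of GG4.
#'
#' @slot group_id one of `"GG1".."GG4"`.
#' @slot mean_lw,mean_area group means (dimensionless; um^2).
#' @slot isolate_sd_lw,isolate_sd_area between-isolate SDs.
#' @slot cell_cv_lw,cell_cv_area within-isolate coefficients of variation.
#' @slot p_bud probability that a cell carries a bud.
#' @slot p_aggregate probability that a cell sits in a multicellular aggregate.
#' @slot aggregate_size_range integer pair, cells per aggregate.
#' @export
setClass("GroupMorphParams", representation(
  group_id = "character",
  mean_lw = "numeric", mean_area = "numeric",
  isolate_sd_lw = "numeric", isolate_sd_area = "numeric",
  cell_cv_lw = "numeric", cell_cv_area = "numeric",
  p_bud = "numeric", p_aggregate = "numeric",
  aggregate_size_range = "integer"
))

setValidity("GroupMorphParams", function(object) {
  msg <- character()
  if (!(object@group_id %in% GG_LEVELS)) msg <- c(msg, "group_id must be GG1..GG4")
  if (!is.finite(object@mean_lw) || object@mean_lw < 1) msg <- c(msg, "mean_lw must be >= 1")
  if (!is.finite(object@mean_area) || object@mean_area <= 0) msg <- c(msg, "mean_area must be > 0")
  for (p in c("p_bud", "p_aggregate")) {
    v <- slot(object, p)
    if (!is.finite(v) || v < 0 || v > 1) msg <- c(msg, paste(p, "must be in [0,1]"))
  }
  if (any(!is.finite(c(object@isolate_sd_lw, object@isolate_sd_area,
                       object@cell_cv_lw, object@cell_cv_area))) ||
      any(c(object@isolate_sd_lw, object@isolate_sd_area,
            object@cell_cv_lw, object@cell_cv_area) < 0))
    msg <- c(msg, "spread parameters must be finite and non-negative")
  if (length(object@aggregate_size_range) != 2L ||
      object@aggregate_size_range[1] < 2L ||
      object@aggregate_size_range[2] < object@aggregate_size_range[1])
    msg <- c(msg, "aggregate_size_range must be an ordered pair with min >= 2")
  if (length(msg)) msg else TRUE
})

#' Isolate-level morphology parameters
#'
#' One isolate's morphology distribution, with means drawn from its group's
#' hyperdistribution by [sampleIsolateParams()]; the cell-level coefficients
#' of variation and bud/aggregate probabilities are inherited from the group.
#'
#' @slot isolate_id isolate label.
#' @slot group_id genetic group of the generating hyperdistribution.
#' @slot mean_lw,mean_area isolate-level means.
#' @slot cell_cv_lw,cell_cv_area within-isolate coefficients of variation.
#' @slot p_bud,p_aggregate per-cell probabilities.
#' @slot aggregate_size_range integer pair, cells per aggregate.
#' @export
setClass("IsolateMorphParams", representation(
  isolate_id = "character", group_id = "character",
  mean_lw = "numeric", mean_area = "numeric",
  cell_cv_lw = "numeric", cell_cv_area = "numeric",
  p_bud = "numeric", p_aggregate = "numeric",
  aggregate_size_range = "integer"
))

setValidity("IsolateMorphParams", function(object) {
  msg <- character()
  if (!(object@group_id %in% GG_LEVELS)) msg <- c(msg, "group_id must be GG1..GG4")
  if (!nzchar(object@isolate_id)) msg <- c(msg, "isolate_id must be non-empty")
  if (!is.finite(object@mean_lw) || object@mean_lw < 1) msg <- c(msg, "mean_lw must be >= 1")
  if (!is.finite(object@mean_area) || object@mean_area <= 0) msg <- c(msg, "mean_area must be > 0")
  if (length(msg)) msg else TRUE
})

#' Rendering configuration for synthetic micrographs
#'
#' Field geometry and optics of the synthetic transmitted-light render:
#' 1280 x 960 px 8-bit grayscale by default, with a spatial calibration
#' (micrometres per pixel), a light background, dark cell rims, Gaussian
#' blur and additive Gaussian noise.
#'
#' @slot width,height field size in pixels (must exceed the 224 px tile).
#' @slot calibration micrometres per pixel (default 0.25).
#' @slot background_level background gray level in \[0, 255\].
#' @slot rim_contrast gray-level drop of the cell rim below background.
#' @slot blur_sigma Gaussian blur sigma in pixels.
#' @slot noise_sd additive Gaussian noise SD in gray levels.
#' @slot rng_seed seed for the render noise (NA = current stream).
#' @export
setClass("RenderConfig", representation(
  width = "integer", height = "integer",
  calibration = "numeric",
  background_level = "numeric", rim_contrast = "numeric",
  blur_sigma = "numeric", noise_sd = "numeric",
  rng_seed = "numeric"
))

setValidity("RenderConfig", function(object) {
  msg <- character()
  if (object@width <= 224L || object@height <= 224L)
    msg <- c(msg, "width and height must exceed 224 px")
  if (!is.finite(object@calibration) || object@calibration <= 0)
    msg <- c(msg, "calibration must be > 0 um/px")
  if (object@background_level < 0 || object@background_level > 255)
    msg <- c(msg, "background_level must be in [0,255]")
  if (object@blur_sigma < 0 || object@noise_sd < 0)
    msg <- c(msg, "blur_sigma and noise_sd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Image manifest
#'
#' Table tying images to isolate, culture and genetic group, with a
#' rejection flag, replicating the two dataset designs of the study
#' (see [buildDataset1Manifest()] and [buildDataset2Manifest()]).
#'
#' @slot table data.frame with columns `image_id`, `isolate_id`,
#'   `culture_id`, `group_id`, `path`, `rejected`.
#' @slot design label of the generating design.
#' @export
setClass("ImageManifest", representation(table = "data.frame", design = "character"))

setValidity("ImageManifest", function(object) {
  need <- c("image_id", "isolate_id", "culture_id", "group_id", "path", "rejected")
  miss <- setdiff(need, names(object@table))
  msg <- character()
  if (length(miss)) msg <- c(msg, paste("manifest lacks columns:", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(object@table$image_id)) msg <- c(msg, "image_id must be unique")
    if (!all(object@table$group_id %in% GG_LEVELS)) msg <- c(msg, "group_id must be GG1..GG4")
    if (!is.logical(object@table$rejected)) msg <- c(msg, "rejected must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' A set of 224 x 224 thumbnails with provenance
#'
#' Tiles cut from full micrographs, stored as a raw (8-bit) array
#' `224 x 224 x n` alongside a provenance table carrying the source image,
#' the grid position and the class label of each tile.
#'
#' @slot pixels raw array `224 x 224 x n` of gray levels.
#' @slot meta data.frame with columns `image_id`, `tile_row`, `tile_col`,
#'   `group_id`.
#' @export
setClass("ThumbnailSet", representation(pixels = "array", meta = "data.frame"))

setValidity("ThumbnailSet", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (!is.raw(object@pixels)) msg <- c(msg, "pixels must be a raw array")
  if (length(d) != 3L || d[1] != 224L || d[2] != 224L)
    msg <- c(msg, "pixels must be 224 x 224 x n")
  else if (nrow(object@meta) != d[3]) msg <- c(msg, "meta rows must match tile count")
  need <- c("image_id", "tile_row", "tile_col", "group_id")
  miss <- setdiff(need, names(object@meta))
  if (length(miss)) msg <- c(msg, paste("meta lacks columns:", paste(miss, collapse = ", ")))
  else if (nrow(object@meta) &&
           (any(!nzchar(object@meta$image_id)) || any(!nzchar(object@meta$group_id))))
    msg <- c(msg, "provenance fields must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Augmentation policy
#'
#' Random transforms applied on the fly to training thumbnails: continuous
#' uniform rotation in \[-45, +45\] degrees, optional horizontal/vertical
#' mirrors, and x/y translations uniform in \[-30, +30\] pixels. Pixels
#' exposed by the transform are filled with the thumbnail's median gray
#' value (or a fixed `fill` level).
#'
#' @slot rotation_range degrees, symmetric pair.
#' @slot mirror_h,mirror_v enable the two mirrors (each drawn with prob 0.5).
#' @slot translation_range pixels, symmetric pair.
#' @slot fill gray level for exposed pixels; `NA` = per-thumbnail median.
#' @export
setClass("AugmentationConfig", representation(
  rotation_range = "numeric", mirror_h = "logical", mirror_v = "logical",
  translation_range = "numeric", fill = "numeric"
))

setValidity("AugmentationConfig", function(object) {
  msg <- character()
  if (length(object@rotation_range) != 2L ||
      !isTRUE(all.equal(object@rotation_range[1], -object@rotation_range[2])))
    msg <- c(msg, "rotation_range must be a symmetric pair")
  if (length(object@translation_range) != 2L ||
      !isTRUE(all.equal(object@translation_range[1], -object@translation_range[2])))
    msg <- c(msg, "translation_range must be a symmetric pair")
  if (!is.na(object@fill) && (object@fill < 0 || object@fill > 255))
    msg <- c(msg, "fill must be in [0,255] or NA")
  if (length(msg)) msg else TRUE
})

#' Stratified train/validation split of a thumbnail set
#'
#' @slot train,validation [ThumbnailSet] objects, disjoint, union = input.
#' @slot fraction per-class training fraction.
#' @export
setClass("DatasetSplit", representation(
  train = "ThumbnailSet", validation = "ThumbnailSet", fraction = "numeric"
))

#' Classifier configuration
#'
#' Configuration of the 4-class thumbnail classifier. The default backbone
#' is a compact convolutional network trained from scratch (four 3x3
#' convolution blocks over a 4x down-pooled input, global average pooling,
#' softmax head); `pretrained_backbone` reserves the transfer-learning path
#' (frozen early layers, boosted head learning rate) for environments that
#' provide pretrained weights.
#'
#' @slot n_classes number of output categories (4 genetic groups).
#' @slot backbone `"compact_cnn"` or `"pretrained_backbone"`.
#' @slot frozen_prefix_layers layers receiving zero learning rate when a
#'   pretrained backbone is used.
#' @slot head_lr_multiplier learning-rate factor of the classification head.
#' @slot optimizer `"adam"` (default) or `"sgd"`.
#' @slot epochs,batch_size,learning_rate,momentum optimizer hyperparameters
#'   (`momentum` doubles as Adam's first-moment decay).
#' @slot rng_seed seed controlling initialisation, shuffling and augmentation.
#' @export
setClass("ClassifierConfig", representation(
  n_classes = "integer", backbone = "character",
  frozen_prefix_layers = "integer", head_lr_multiplier = "numeric",
  optimizer = "character", epochs = "integer", batch_size = "integer",
  learning_rate = "numeric", momentum = "numeric",
  rng_seed = "numeric"
))

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (object@n_classes != 4L) msg <- c(msg, "n_classes must be 4 for this study")
  if (!(object@backbone %in% c("compact_cnn", "pretrained_backbone")))
    msg <- c(msg, "backbone must be 'compact_cnn' or 'pretrained_backbone'")
  if (!(object@optimizer %in% c("adam", "sgd")))
    msg <- c(msg, "optimizer must be 'adam' or 'sgd'")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@head_lr_multiplier <= 0) msg <- c(msg, "head_lr_multiplier must be > 0")
  if (object@batch_size < 1L) msg <- c(msg, "batch_size must be >= 1")
  if (object@learning_rate <= 0) msg <- c(msg, "learning_rate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Compact CNN model handle
#'
#' Weights, configuration, class order and training history of the compact
#' convolutional classifier. Weights live in an ordinary R list (one matrix
#' and bias vector per layer) so models serialize with base R.
#'
#' @slot weights named list of layer weights.
#' @slot config the [ClassifierConfig-class] used to build it.
#' @slot classes class label order of the output probabilities.
#' @slot history per-epoch data.frame (`epoch`, `train_loss`, `val_accuracy`).
#' @slot trained logical flag.
#' @export
setClass("CompactCNN", representation(
  weights = "list", config = "ClassifierConfig",
  classes = "character", history = "data.frame", trained = "logical"
))

#' Classification metric panel
#'
#' Confusion matrix plus the standard panel: accuracy, error, and per-class
#' and macro-averaged sensitivity, specificity, precision, false-positive
#' rate and F1 (one-vs-rest definitions). `error = 1 - accuracy` and per
#' class `specificity + FPR = 1` by construction.
#'
#' @slot confusion 4x4 count matrix, rows = truth, columns = prediction.
#' @slot accuracy,error overall rates.
#' @slot per_class data.frame of one-vs-rest metrics per class.
#' @slot macro named numeric of unweighted class means.
#' @export
setClass("MetricsReport", representation(
  confusion = "matrix", accuracy = "numeric", error = "numeric",
  per_class = "data.frame", macro = "numeric"
))

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (any(object@confusion < 0)) msg <- c(msg, "confusion counts must be non-negative")
  if (!isTRUE(all.equal(object@error, 1 - object@accuracy)))
    msg <- c(msg, "error must equal 1 - accuracy")
  if (length(msg)) msg else TRUE
})

#' RAPD profile table
#'
#' Categorical RAPD-PCR fingerprint profiles per isolate for the primers
#' OPA-02, OPA-03 and OPA-09, alongside the isolate's microsatellite genetic
#' group. See [rapdProfileTable()] for the packaged synthetic fixture.
#'
#' @slot table data.frame with columns `isolate_id`, `group_id`, `opa02`,
#'   `opa03`, `opa09`.
#' @export
setClass("RAPDProfileTable", representation(table = "data.frame"))

setValidity("RAPDProfileTable", function(object) {
  need <- c("isolate_id", "group_id", "opa02", "opa03", "opa09")
  miss <- setdiff(need, names(object@table))
  msg <- character()
  if (length(miss)) msg <- c(msg, paste("table lacks columns:", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(object@table$isolate_id))
      msg <- c(msg, "each isolate must appear once (one profile per primer)")
    if (nrow(object@table) && !all(object@table$group_id %in% GG_LEVELS))
      msg <- c(msg, "group_id must be GG1..GG4")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "GroupMorphParams", function(object) {
  cat(sprintf("GroupMorphParams %s: mean l/w %.2f, mean area %.1f um^2\n",
              object@group_id, object@mean_lw, object@mean_area))
  cat(sprintf("  isolate SD (lw, area): %.2f, %.1f; cell CV (lw, area): %.2f, %.2f\n",
              object@isolate_sd_lw, object@isolate_sd_area,
              object@cell_cv_lw, object@cell_cv_area))
  cat(sprintf("  p(bud) %.2f, p(aggregate) %.2f, aggregate size %d-%d\n",
              object@p_bud, object@p_aggregate,
              object@aggregate_size_range[1], object@aggregate_size_range[2]))
})

setMethod("show", "IsolateMorphParams", function(object) {
  cat(sprintf("IsolateMorphParams %s (%s): mean l/w %.3f, mean area %.2f um^2\n",
              object@isolate_id, object@group_id, object@mean_lw, object@mean_area))
})

setMethod("show", "ImageManifest", function(object) {
  tab <- object@table
  keep <- !tab$rejected
  cat(sprintf("ImageManifest (%s): %d images (%d rejected)\n",
              object@design, nrow(tab), sum(tab$rejected)))
  print(table(factor(tab$group_id[keep], levels = GG_LEVELS)))
})

setMethod("show", "ThumbnailSet", function(object) {
  cat(sprintf("ThumbnailSet: %d thumbnails of 224 x 224 px\n", nThumbnails(object)))
  if (nThumbnails(object))
    print(table(factor(object@meta$group_id, levels = unique(object@meta$group_id))))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d training / %d validation thumbnails (fraction %.2f)\n",
              nThumbnails(object@train), nThumbnails(object@validation), object@fraction))
})

setMethod("show", "CompactCNN", function(object) {
  cat(sprintf("CompactCNN (%s): %d classes [%s], %s\n",
              object@config@backbone, object@config@n_classes,
              paste(object@classes, collapse = ", "),
              if (object@trained) sprintf("trained %d epochs", nrow(object@history))
              else "untrained"))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.4f, error %.4f\n",
              object@accuracy, object@error))
  cat("Macro averages:\n"); print(round(object@macro, 4))
  cat("Confusion matrix (rows = truth):\n"); print(object@confusion)
})

setMethod("show", "RAPDProfileTable", function(object) {
  cat(sprintf("RAPDProfileTable: %d isolates, primers OPA-02, OPA-03, OPA-09\n",
              nrow(object@table)))
  if (nrow(object@table))
    print(table(factor(object@table$group_id, levels = GG_LEVELS)))
})

## ---- accessors ----

#' Accessors for the package's S4 containers
#'
#' @param x an object of the documented class.
#' @return `manifestTable` and `profileTable` return the underlying
#'   data.frame; `nThumbnails` the tile count; `thumbnailMeta` the provenance
#'   table; `getThumbnail` one tile as an integer gray-level matrix;
#'   `modelHistory` the per-epoch training history.
#' @name accessors
NULL

#' @rdname accessors
#' @export
manifestTable <- function(x) {
  stopifnot(is(x, "ImageManifest"))
  x@table
}

#' @rdname accessors
#' @export
profileTable <- function(x) {
  stopifnot(is(x, "RAPDProfileTable"))
  x@table
}

#' @rdname accessors
#' @export
nThumbnails <- function(x) {
  stopifnot(is(x, "ThumbnailSet"))
  dim(x@pixels)[3]
}

#' @rdname accessors
#' @export
thumbnailMeta <- function(x) {
  stopifnot(is(x, "ThumbnailSet"))
  x@meta
}

#' @rdname accessors
#' @param i tile index.
#' @export
getThumbnail <- function(x, i) {
  stopifnot(is(x, "ThumbnailSet"), i >= 1L, i <= nThumbnails(x))
  matrix(as.integer(x@pixels[, , i]), nrow = 224L)
}

#' @rdname accessors
#' @export
modelHistory <- function(x) {
  stopifnot(is(x, "CompactCNN"))
  x@history
}
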