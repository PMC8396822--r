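## 4-class thumbnail classifier and image-level majority vote.
##
## The default backbone is a compact convolutional network trained from
## scratch (defined in src/cnn.cpp): 2x average pooling of the 224x224
## grayscale tile to 112x112, four 3x3 convolution blocks (16/32/64/64
## channels, batch norm + ReLU, 2x max pooling after the first three),
## global average pooling and a softmax head. The transfer-learning path of the study
## (pretrained backbone, frozen prefix, boosted head learning rate) is
## reserved for environments that can supply pretrained weights; its
## freeze/multiplier mechanics are implemented as per-layer learning-rate
## multipliers that the training loop always honours.

CNN_LAYERS <- c("conv1", "conv2", "conv3", "conv4", "head")

#' Construct a classifier configuration
#'
#' @param n_classes output categories; fixed at 4 (the genetic groups).
#' @param backbone `"compact_cnn"` (default) or `"pretrained_backbone"`.
#' @param frozen_prefix_layers leading layers given zero learning rate when
#'   a pretrained backbone is used (default 10, counted over that backbone's
#'   published layer order).
#' @param head_lr_multiplier learning-rate factor of the classification
#'   head (default 5).
#' @param epochs training epochs; 64 in the full design, 10 in the
#'   desk-scale test profile.
#' @param optimizer `"adam"` (default) or `"sgd"` with momentum. Adam is the
#'   default because the batch-normalised compact net trains from scratch
#'   within the 10-epoch desk profile, which plain SGD does not reach.
#' @param batch_size,learning_rate,momentum optimizer hyperparameters
#'   (defaults 32, 2e-3, 0.9; `momentum` is Adam's first-moment decay).
#'   The base rate follows a half-cosine decay over the configured epochs.
#'   These settings are package conventions, exposed here rather than fixed.
#' @param rng_seed seed controlling initialisation, shuffling and
#'   augmentation draws.
#' @return A [ClassifierConfig-class].
#' @export
classifierConfig <- function(n_classes = 4L, backbone = "compact_cnn",
                             frozen_prefix_layers = 10L,
                             head_lr_multiplier = 5,
                             optimizer = "adam",
                             epochs = 64L, batch_size = 32L,
                             learning_rate = 2e-3, momentum = 0.9,
                             rng_seed = NA_real_) {
  new("ClassifierConfig", n_classes = as.integer(n_classes),
      backbone = backbone,
      frozen_prefix_layers = as.integer(frozen_prefix_layers),
      head_lr_multiplier = head_lr_multiplier, optimizer = optimizer,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, momentum = momentum,
      rng_seed = as.numeric(rng_seed))
}

## He-normal conv and head weights; unit batch-norm scale, zero shift;
## running statistics start at (0, 1)
initCompactWeights <- function(rng_seed = NULL) {
  shapes <- list(W1 = c(9, 16), W2 = c(144, 32), W3 = c(288, 64),
                 W4 = c(576, 64), W5 = c(64, 4))
  withSeed(rng_seed, {
    w <- list()
    for (nm in names(shapes)) {
      sh <- shapes[[nm]]
      k <- sub("W", "", nm)
      w[[nm]] <- matrix(rnorm(prod(sh), 0, sqrt(2 / sh[1])), sh[1], sh[2])
      w[[paste0("b", k)]] <- numeric(sh[2])
      if (nm != "W5") {
        w[[paste0("g", k)]] <- rep(1, sh[2])
        w[[paste0("rm", k)]] <- numeric(sh[2])
        w[[paste0("rv", k)]] <- rep(1, sh[2])
      }
    }
    w
  })
}

## parameter name -> architectural layer (buffers rm*/rv* excluded)
TRAINABLE <- c("W1", "g1", "b1", "W2", "g2", "b2", "W3", "g3", "b3",
               "W4", "g4", "b4", "W5", "b5")
parLayer <- function(nm) CNN_LAYERS[as.integer(sub("^[Wgb]", "", nm))]

#' Build an untrained classifier
#'
#' @param cfg a [ClassifierConfig-class].
#' @param classes class label order (default GG1..GG4).
#' @return An untrained [CompactCNN-class] mapping a 224 x 224 grayscale
#'   thumbnail to a 4-way probability vector.
#' @examples
#' model <- buildClassifier(classifierConfig(epochs = 10L, rng_seed = 1))
#' @export
buildClassifier <- function(cfg = classifierConfig(), classes = GG_LEVELS) {
  stopifnot(is(cfg, "ClassifierConfig"))
  validObject(cfg)
  if (cfg@backbone == "pretrained_backbone")
    stop("backbone 'pretrained_backbone' is unavailable: no pretrained ",
         "weights ship with this package and none can be downloaded in an ",
         "offline environment. Use backbone = 'compact_cnn', or place ",
         "pretrained weights on disk and load them into a CompactCNN via ",
         "its 'weights' slot.", call. = FALSE)
  seed <- if (is.na(cfg@rng_seed)) NULL else cfg@rng_seed
  new("CompactCNN", weights = initCompactWeights(seed), config = cfg,
      classes = classes,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_accuracy = numeric()),
      trained = FALSE)
}

## stack thumbnails (by index) into a 224 x 224 x n numeric array,
## optionally augmenting each tile
thumbArray <- function(ts, idx, aug_cfg = NULL) {
  arr <- array(0, dim = c(TILE, TILE, length(idx)))
  for (k in seq_along(idx)) {
    m <- getThumbnail(ts, idx[k])
    if (!is.null(aug_cfg)) m <- augmentThumbnail(m, aug_cfg)
    arr[, , k] <- m
  }
  arr
}

#' Per-layer learning-rate multipliers for a model
#'
#' All ones for the from-scratch compact net; under the transfer-learning
#' scheme the frozen prefix receives 0 and the head `head_lr_multiplier`.
#'
#' @param model a [CompactCNN-class].
#' @return Named numeric vector over the 5 layers.
#' @export
layerLRMultipliers <- function(model) {
  stopifnot(is(model, "CompactCNN"))
  cfg <- model@config
  mult <- rep(1, length(CNN_LAYERS))
  names(mult) <- CNN_LAYERS
  if (cfg@backbone == "pretrained_backbone") {
    nfrozen <- min(cfg@frozen_prefix_layers, length(CNN_LAYERS) - 1L)
    mult[seq_len(nfrozen)] <- 0
    mult["head"] <- cfg@head_lr_multiplier
  }
  mult
}

#' Train the classifier on a stratified split
#'
#' Minimises cross-entropy by mini-batch gradient descent (Adam by default,
#' plain SGD with momentum available); training tiles are augmented on the
#' fly each epoch, validation tiles never are. Batch-normalisation running
#' statistics are tracked during training and used at inference. The
#' per-epoch history records mean training loss and validation thumbnail
#' accuracy. Deterministic given `cfg@rng_seed`.
#'
#' @param model an untrained or trained [CompactCNN-class].
#' @param split a [DatasetSplit-class].
#' @param aug_cfg an [AugmentationConfig-class] for the training tiles.
#' @param cfg optional [ClassifierConfig-class] overriding the model's.
#' @return The trained [CompactCNN-class] with filled history.
#' @export
trainClassifier <- function(model, split, aug_cfg = augmentationConfig(),
                            cfg = NULL) {
  stopifnot(is(model, "CompactCNN"), is(split, "DatasetSplit"))
  if (is.null(cfg)) cfg <- model@config
  if (nThumbnails(split@train) == 0L)
    stop("training set is empty", call. = FALSE)
  y_train <- factor(split@train@meta$group_id, levels = model@classes)
  if (anyNA(y_train)) stop("training labels outside the model's classes", call. = FALSE)
  if (any(table(y_train) == 0L))
    stop("training set has an empty class: ",
         paste(levels(y_train)[table(y_train) == 0L], collapse = ", "),
         call. = FALSE)

  w <- model@weights
  zero <- lapply(w[TRAINABLE], function(x) x * 0)
  vel <- zero; m1 <- zero; m2 <- zero
  step <- 0L
  adam <- cfg@optimizer == "adam"
  lr_mult <- layerLRMultipliers(model)
  n <- nThumbnails(split@train)
  bs <- min(cfg@batch_size, n)
  labels0 <- as.integer(y_train) - 1L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_accuracy = numeric())
  seed <- if (is.na(cfg@rng_seed)) NULL else cfg@rng_seed

  run <- function() {
    for (ep in seq_len(cfg@epochs)) {
      ## half-cosine learning-rate decay over the configured epochs
      lr_ep <- cfg@learning_rate * 0.5 * (1 + cos(pi * (ep - 1) / cfg@epochs))
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        x <- thumbArray(split@train, idx, aug_cfg)
        res <- cpp_cnn_grad(x, labels0[idx], w)
        g <- res$grads
        step <<- step + 1L
        for (nm in TRAINABLE) {
          lr <- lr_ep * lr_mult[[parLayer(nm)]]
          if (lr == 0) next
          if (adam) {
            m1[[nm]] <<- cfg@momentum * m1[[nm]] + (1 - cfg@momentum) * g[[nm]]
            m2[[nm]] <<- 0.999 * m2[[nm]] + 0.001 * g[[nm]]^2
            mh <- m1[[nm]] / (1 - cfg@momentum^step)
            vh <- m2[[nm]] / (1 - 0.999^step)
            w[[nm]] <<- w[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
          } else {
            vel[[nm]] <<- cfg@momentum * vel[[nm]] - lr * g[[nm]]
            w[[nm]] <<- w[[nm]] + vel[[nm]]
          }
        }
        for (nm in names(res$running)) w[[nm]] <<- res$running[[nm]]
        losses <- c(losses, res$loss)
      }
      val_acc <- NA_real_
      if (nThumbnails(split@validation) > 0L) {
        pv <- predictWithWeights(w, split@validation, model@classes)
        val_acc <- mean(pv$label == split@validation@meta$group_id)
      }
      history <<- rbind(history, data.frame(
        epoch = ep, train_loss = mean(losses), val_accuracy = val_acc))
    }
  }
  withSeed(seed, run())

  model@weights <- w
  model@history <- history
  model@trained <- TRUE
  model
}

## forward pass over a ThumbnailSet in chunks; returns probs + argmax labels
predictWithWeights <- function(w, ts, classes, chunk = 256L) {
  n <- nThumbnails(ts)
  probs <- matrix(NA_real_, n, length(classes),
                  dimnames = list(NULL, classes))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    probs[idx, ] <- cpp_cnn_forward(thumbArray(ts, idx), w)
  }
  list(probs = probs, label = classes[max.col(probs, ties.method = "first")])
}

#' Predict class probabilities for every thumbnail in a set
#'
#' @param model a [CompactCNN-class].
#' @param thumbs a [ThumbnailSet-class].
#' @return data.frame: provenance columns, one probability column per class
#'   (`p_GG1` ...), and the argmax `label`.
#' @export
predictThumbnails <- function(model, thumbs) {
  stopifnot(is(model, "CompactCNN"), is(thumbs, "ThumbnailSet"))
  if (nThumbnails(thumbs) == 0L)
    stop("no thumbnails to predict", call. = FALSE)
  pv <- predictWithWeights(model@weights, thumbs, model@classes)
  out <- thumbs@meta
  colnames(pv$probs) <- paste0("p_", model@classes)
  cbind(out, as.data.frame(pv$probs), label = pv$label,
        stringsAsFactors = FALSE)
}

#' Assign a genetic group to a whole image by majority vote over its tiles
#'
#' The image is tiled, each tile is classified, and the most frequently
#' predicted group is assigned to the image. Vote ties are broken by the
#' highest summed tile probability and flagged.
#'
#' @param model a trained [CompactCNN-class].
#' @param image gray-level matrix, at least 224 px in both dimensions.
#' @param image_id identifier recorded in the result.
#' @return list with `image_id`, `votes` (named integer over classes),
#'   `assigned`, `tie` (logical), and the per-tile prediction table.
#' @export
predictImage <- function(model, image, image_id = "image") {
  stopifnot(is(model, "CompactCNN"))
  ts <- tileImage(image, image_id, group_id = "unknown")
  if (nThumbnails(ts) == 0L)
    stop("image is smaller than one 224 x 224 thumbnail; cannot predict",
         call. = FALSE)
  pred <- predictThumbnails(model, ts)
  tallyVotes(pred, model@classes, image_id)
}

## vote tally with the tie rule; exported for testing vote semantics alone
#' @rdname predictImage
#' @param tile_predictions data.frame as returned by [predictThumbnails()].
#' @param classes class order.
#' @export
tallyVotes <- function(tile_predictions, classes = GG_LEVELS,
                       image_id = "image") {
  votes <- table(factor(tile_predictions$label, levels = classes))
  votes <- setNames(as.integer(votes), classes)
  top <- which(votes == max(votes))
  tie <- length(top) > 1L
  if (tie) {
    psum <- vapply(classes[top], function(cl)
      sum(tile_predictions[[paste0("p_", cl)]]), numeric(1))
    assigned <- classes[top[which.max(psum)]]
  } else assigned <- classes[top]
  list(image_id = image_id, votes = votes, assigned = assigned, tie = tie,
       tiles = tile_predictions)
}

#' Predict many images and collect an image-level prediction table
#'
#' @param model a trained [CompactCNN-class].
#' @param images named list of gray-level matrices (names = image ids).
#' @return data.frame: `image_id`, one vote column per class, `assigned`,
#'   `tie`.
#' @export
predictImages <- function(model, images) {
  stopifnot(is.list(images), length(images) > 0L, !is.null(names(images)))
  rows <- lapply(names(images), function(id) {
    p <- predictImage(model, images[[id]], id)
    c(list(image_id = id), as.list(p$votes), list(assigned = p$assigned,
                                                  tie = p$tie))
  })
  do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
}
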