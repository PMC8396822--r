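## Classification evaluation: confusion matrix, the one-vs-rest metric
## panel (accuracy, error, sensitivity, specificity, precision, FPR, F1)
## and image-level vote accuracy for independent test sets.

#' Build a confusion matrix from truth and prediction labels
#'
#' @param truth,predicted equal-length label vectors over the 4 groups.
#' @param classes class order (default GG1..GG4).
#' @return Integer count matrix, rows = true class, columns = predicted.
#' @examples
#' confusionMatrix(c("GG1", "GG2"), c("GG1", "GG3"))
#' @export
confusionMatrix <- function(truth, predicted, classes = GG_LEVELS) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Compute the classification metric panel from a confusion matrix
#'
#' Accuracy is trace/total; per class, one-vs-rest TP/FP/FN/TN give
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' false-positive rate FP/(FP+TN) and F1 = 2PR/(P+R). Macro values are
#' unweighted class means. Ratios with zero denominators are reported as
#' `NA` with a warning and excluded from the macro means. By construction
#' `error = 1 - accuracy` and, per class, `specificity + FPR = 1`.
#'
#' @param cm square count matrix with class dimnames (rows = truth).
#' @return A [MetricsReport-class].
#' @export
computeMetrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  acc <- sum(diag(cm)) / total

  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  per <- lapply(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    prec <- ratio(tp, tp + fp)
    fpr <- ratio(fp, fp + tn)
    f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    data.frame(class = classes[k], sensitivity = sens, specificity = spec,
               precision = prec, fpr = fpr, f1 = f1,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (anyNA(per[, -1]))
    warning("some per-class metrics are undefined (zero denominator); ",
            "excluded from macro averages", call. = FALSE)
  macro <- vapply(c("sensitivity", "specificity", "precision", "fpr", "f1"),
                  function(nm) mean(per[[nm]], na.rm = TRUE), numeric(1))
  new("MetricsReport", confusion = cm, accuracy = acc, error = 1 - acc,
      per_class = per, macro = macro)
}

#' Image-level vote accuracy against a manifest
#'
#' Fraction of images whose voted (majority-assigned) group equals the true
#' group, with a per-group breakdown; the accuracy measure used on the
#' independent test design.
#'
#' @param truth an [ImageManifest-class] or data.frame with `image_id` and
#'   `group_id`.
#' @param predictions data.frame with `image_id` and `assigned` (as from
#'   [predictImages()]).
#' @return list: `accuracy`, `n`, `per_group` data.frame (`group_id`, `n`,
#'   `n_correct`, `accuracy`).
#' @export
imageLevelAccuracy <- function(truth, predictions) {
  if (is(truth, "ImageManifest")) truth <- manifestTable(truth)
  stopifnot(is.data.frame(truth), all(c("image_id", "group_id") %in% names(truth)),
            is.data.frame(predictions),
            all(c("image_id", "assigned") %in% names(predictions)))
  if ("rejected" %in% names(truth)) truth <- truth[!truth$rejected, ]
  missing <- setdiff(truth$image_id, predictions$image_id)
  if (length(missing))
    stop("no prediction for image(s): ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  pred <- predictions$assigned[match(truth$image_id, predictions$image_id)]
  correct <- pred == truth$group_id
  per <- do.call(rbind, lapply(unique(truth$group_id), function(g) {
    sel <- truth$group_id == g
    data.frame(group_id = g, n = sum(sel), n_correct = sum(correct[sel]),
               accuracy = mean(correct[sel]), stringsAsFactors = FALSE)
  }))
  list(accuracy = mean(correct), n = nrow(truth), per_group = per)
}
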