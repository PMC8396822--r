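## Dataset designs: 74 isolates in 4 genetic groups; dataset1 is the
## training/validation image collection (10 images x 3 cultures per isolate
## minus 7 rejected images), dataset2 the independent 233-image test set.

#' Isolate-to-genetic-group membership of the 74-isolate panel
#'
#' The study panel: 12 GG1, 7 GG2, 50 GG3 and 5 GG4 isolates (collection
#' strains carry their collection names, winery isolates are numbered).
#'
#' @return data.frame with columns `isolate_id`, `group_id`.
#' @export
table1Membership <- function() {
  gg1 <- c("1", "14", "25", "26", "27", "30", "49", "61", "62",
           "LO2E2", "CDR3", "CDR12")
  gg2 <- c("2", "4", "6", "11", "17", "19", "20")
  gg3 <- c("3", "5", "7", "8", "9", "10", "12", "13", "15", "16", "18",
           "21", "22", "23", "24", "28", "29", "31", "32", "33", "34",
           "35", "36", "37", "38", "39", "40", "41", "42", "43", "44",
           "45", "46", "47", "48", "50", "51", "52", "53", "54", "55",
           "56", "57", "58", "59", "60", "64", "LO6/036", "CDR9", "CDR11")
  gg4 <- c("63", "CDR217", "CDR219", "LO417", "AWRI1499")
  data.frame(
    isolate_id = c(gg1, gg2, gg3, gg4),
    group_id = rep(GG_LEVELS, times = c(length(gg1), length(gg2),
                                        length(gg3), length(gg4))),
    stringsAsFactors = FALSE)
}

#' Default image rejections of the dataset1 design
#'
#' Seven images were rejected for artifacts: six of isolate 30 and one of
#' isolate 56.
#'
#' @return data.frame with columns `isolate_id`, `n_rejected`.
#' @export
defaultRejections <- function() {
  data.frame(isolate_id = c("30", "56"), n_rejected = c(6L, 1L),
             stringsAsFactors = FALSE)
}

#' Build the dataset1 manifest (training/validation design)
#'
#' 10 images per culture and 3 independent cultures for each of the 74
#' isolates, with per-isolate rejection counts flagged (rejections are taken
#' from the start of the isolate's first culture). At the defaults the
#' non-rejected per-group counts are 354 (GG1), 210 (GG2), 1499 (GG3) and
#' 150 (GG4).
#'
#' @param membership isolate/group table as from [table1Membership()].
#' @param images_per_culture,cultures design constants (defaults 10 and 3).
#' @param rejections data.frame (`isolate_id`, `n_rejected`) or NULL.
#' @return An [ImageManifest-class].
#' @examples
#' m <- buildDataset1Manifest()
#' table(manifestTable(m)$group_id[!manifestTable(m)$rejected])
#' @export
buildDataset1Manifest <- function(membership = table1Membership(),
                                  images_per_culture = 10L, cultures = 3L,
                                  rejections = defaultRejections()) {
  stopifnot(is.data.frame(membership),
            all(c("isolate_id", "group_id") %in% names(membership)))
  if (!is.null(rejections) && nrow(rejections)) {
    unknown <- setdiff(rejections$isolate_id, membership$isolate_id)
    if (length(unknown))
      stop("rejections name isolates absent from the membership table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(rejections$n_rejected < 0) ||
        any(rejections$n_rejected > images_per_culture * cultures))
      stop("rejection counts outside the per-isolate image count", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(membership)), function(i) {
    iso <- membership$isolate_id[i]
    grp <- membership$group_id[i]
    culture <- rep(seq_len(cultures), each = images_per_culture)
    img_in_culture <- rep(seq_len(images_per_culture), times = cultures)
    n <- cultures * images_per_culture
    nrej <- 0L
    if (!is.null(rejections)) {
      hit <- rejections$isolate_id == iso
      if (any(hit)) nrej <- sum(rejections$n_rejected[hit])
    }
    iso_safe <- gsub("[^A-Za-z0-9]", "", iso)
    data.frame(
      image_id = sprintf("d1_%s_c%d_i%02d", iso_safe, culture, img_in_culture),
      isolate_id = iso,
      culture_id = sprintf("%s_c%d", iso_safe, culture),
      group_id = grp,
      path = NA_character_,
      rejected = seq_len(n) <= nrej,
      stringsAsFactors = FALSE)
  })
  new("ImageManifest", table = do.call(rbind, rows), design = "dataset1")
}

#' Per-isolate design of the 233-image independent test set
#'
#' The 15 isolate entries of the dataset2 design with their culture and
#' image counts; per-group image totals are 46/63/66/58 for GG1-GG4.
#'
#' @return data.frame with columns `isolate_id`, `group_id`, `n_cultures`,
#'   `n_images`.
#' @export
dataset2Design <- function() {
  data.frame(
    isolate_id = c("14", "49", "LO2E2",
                   "2", "11", "17", "20",
                   "7", "9", "32", "60",
                   "63", "CDR219", "LO417", "AWRI1499"),
    group_id = rep(GG_LEVELS, times = c(3L, 4L, 4L, 4L)),
    n_cultures = c(1L, 2L, 2L,
                   1L, 2L, 2L, 2L,
                   1L, 2L, 2L, 2L,
                   1L, 2L, 2L, 2L),
    n_images = c(10L, 17L, 19L,
                 10L, 18L, 18L, 17L,
                 10L, 19L, 18L, 19L,
                 10L, 16L, 16L, 16L),
    stringsAsFactors = FALSE)
}

#' Build the dataset2 manifest (independent test design)
#'
#' Image counts spanning two cultures are split as evenly as possible
#' (ceiling in the first culture). The default design totals 233 images.
#'
#' @param design data.frame as from [dataset2Design()].
#' @return An [ImageManifest-class].
#' @examples
#' nrow(manifestTable(buildDataset2Manifest()))  # 233
#' @export
buildDataset2Manifest <- function(design = dataset2Design()) {
  stopifnot(is.data.frame(design))
  need <- c("isolate_id", "group_id", "n_cultures", "n_images")
  if (nrow(design) == 0L)
    return(new("ImageManifest",
               table = data.frame(image_id = character(), isolate_id = character(),
                                  culture_id = character(), group_id = character(),
                                  path = character(), rejected = logical(),
                                  stringsAsFactors = FALSE),
               design = "dataset2"))
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(design$n_images < 0) || any(design$n_cultures < 1))
    stop("image and culture counts must be non-negative / positive", call. = FALSE)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    iso <- design$isolate_id[i]; ncult <- design$n_cultures[i]
    nimg <- design$n_images[i]
    per <- diff(round(seq(0, nimg, length.out = ncult + 1L)))
    per <- sort(per, decreasing = TRUE)  # ceiling-first split across cultures
    culture <- rep(seq_len(ncult), times = per)
    within <- unlist(lapply(per, seq_len), use.names = FALSE)
    iso_safe <- gsub("[^A-Za-z0-9]", "", iso)
    data.frame(
      image_id = sprintf("d2_%s_c%d_i%02d", iso_safe, culture, within),
      isolate_id = iso,
      culture_id = sprintf("%s_c%d", iso_safe, culture),
      group_id = design$group_id[i],
      path = NA_character_,
      rejected = FALSE,
      stringsAsFactors = FALSE)
  })
  new("ImageManifest", table = do.call(rbind, rows), design = "dataset2")
}

#' Non-rejected image counts per genetic group
#'
#' @param manifest an [ImageManifest-class].
#' @return Named integer vector over GG1..GG4.
#' @export
manifestGroupCounts <- function(manifest) {
  stopifnot(is(manifest, "ImageManifest"))
  tab <- manifest@table
  keep <- !tab$rejected
  counts <- table(factor(tab$group_id[keep], levels = GG_LEVELS))
  setNames(as.integer(counts), GG_LEVELS)
}
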