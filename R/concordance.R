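## RAPD-PCR profile / genetic-group concordance. Profiles are categorical
## fingerprint labels per primer; a primer identifies the genetic groups
## when its profile partition refines the group partition (each profile
## carried by exactly one group; a group split across several profiles is
## acceptable).

PRIMERS <- c("OPA-02" = "opa02", "OPA-03" = "opa03", "OPA-09" = "opa09")

#' Construct or load a RAPD profile table
#'
#' `rapdProfileTable()` with no arguments loads the packaged synthetic
#' fixture (`inst/extdata/rapd_profiles_synthetic.csv`): 74 isolates whose
#' profiles realise the study's reported structure — 4 profiles for OPA-02
#' (C2 shared by GG3 and GG4) and OPA-03 (B3 shared by GG2 and GG3), and 5
#' for OPA-09, where each profile maps to a single group (A9 to GG1, B9 to
#' GG2, D9 to GG4; GG3 split between C9 and E9). The within-GG3 splits are
#' a package convention: the study reports which profiles exist and which
#' groups share them, not the isolate-by-profile counts.
#'
#' @param table optional data.frame with columns `isolate_id`, `group_id`,
#'   `opa02`, `opa03`, `opa09`.
#' @return A [RAPDProfileTable-class].
#' @examples
#' countProfiles(rapdProfileTable(), "OPA-09")  # 5
#' @export
rapdProfileTable <- function(table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "rapd_profiles_synthetic.csv",
                        package = "bruxmorph", mustWork = TRUE)
    table <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  new("RAPDProfileTable", table = table)
}

#' Read a RAPD profile table from CSV
#'
#' @param path CSV file with columns `isolate_id`, `group_id`, `opa02`,
#'   `opa03`, `opa09`.
#' @return A [RAPDProfileTable-class].
#' @export
readRAPDProfiles <- function(path) {
  rapdProfileTable(read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character"))
}

primerColumn <- function(table, primer) {
  key <- toupper(primer)
  if (!(key %in% names(PRIMERS)))
    stop("unknown primer '", primer, "'; available: ",
         paste(names(PRIMERS), collapse = ", "), call. = FALSE)
  table@table[[PRIMERS[[key]]]]
}

#' Count distinct profiles observed for a primer
#'
#' @param table a [RAPDProfileTable-class].
#' @param primer one of `"OPA-02"`, `"OPA-03"`, `"OPA-09"`.
#' @return Number of distinct profile letters (0 for an empty table).
#' @export
countProfiles <- function(table, primer) {
  stopifnot(is(table, "RAPDProfileTable"))
  length(unique(primerColumn(table, primer)))
}

#' Map each profile of a primer to the genetic groups carrying it
#'
#' @inheritParams countProfiles
#' @return Named list: profile letter -> sorted character vector of groups.
#' @examples
#' profileGroupMap(rapdProfileTable(), "OPA-02")$C2  # GG3 GG4
#' @export
profileGroupMap <- function(table, primer) {
  stopifnot(is(table, "RAPDProfileTable"))
  prof <- primerColumn(table, primer)
  grp <- table@table$group_id
  out <- lapply(split(grp, prof), function(g) sort(unique(g)))
  out[order(names(out))]
}

#' Does a primer's profile partition refine the genetic-group partition?
#'
#' TRUE iff every profile is carried by exactly one genetic group (a group
#' split across several profiles still refines); otherwise the profiles
#' shared across groups are listed.
#'
#' @inheritParams countProfiles
#' @return list: `refines` (logical), `offending` (character vector of
#'   profiles carried by more than one group).
#' @examples
#' refinesGroups(rapdProfileTable(), "OPA-09")$refines  # TRUE
#' @export
refinesGroups <- function(table, primer) {
  stopifnot(is(table, "RAPDProfileTable"))
  map <- profileGroupMap(table, primer)
  offending <- names(map)[vapply(map, length, integer(1)) > 1L]
  list(refines = length(offending) == 0L, offending = offending)
}
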