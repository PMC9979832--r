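# Unit x species presence/absence matrices.

#' Build a unit-by-species presence/absence matrix
#'
#' Occurrence data are reduced to binary incidence to damp differences in
#' sampling methods and effort between units: a cell is 1 when at least one
#' record of that species was assigned to that unit, whatever the record
#' count. Records assigned to no unit are counted, never silently dropped.
#'
#' @param records curated occurrence data frame.
#' @param assignment either a scheme (see [make_watling_scheme()] and
#'   friends), a character vector of unit ids parallel to `records` (`NA` =
#'   unassigned), or a function mapping the records data frame to such a
#'   vector.
#' @return binary integer matrix, units in rows and species in columns.
#'   When a scheme is given, all its units appear as rows (possibly
#'   all-zero) in scheme order. Attributes: `n_unassigned` (records mapping
#'   to no unit).
#' @export
build_presence_absence <- function(records, assignment) {
  records <- as_records(records)
  if (inherits(assignment, "biogeo_scheme")) {
    unit_ids <- assign_units(records, assignment)
    all_units <- assignment$units$unit_id
  } else if (is.function(assignment)) {
    unit_ids <- assignment(records)
    all_units <- unique(unit_ids[!is.na(unit_ids)])
  } else {
    unit_ids <- as.character(assignment)
    if (length(unit_ids) != nrow(records))
      stop_input("assignment vector must have one entry per record")
    all_units <- unique(unit_ids[!is.na(unit_ids)])
  }
  assigned <- !is.na(unit_ids)
  species <- sort(unique(records$taxon_name[assigned]))
  m <- matrix(0L, nrow = length(all_units), ncol = length(species),
              dimnames = list(all_units, species))
  if (any(assigned)) {
    idx <- cbind(match(unit_ids[assigned], all_units),
                 match(records$taxon_name[assigned], species))
    m[idx] <- 1L
  }
  attr(m, "n_unassigned") <- sum(!assigned)
  m
}

#' Drop units without occurrences
#'
#' Biogeographical units in which no species was recorded carry no
#' compositional information and are removed before the dissimilarity
#' analysis; species columns that thereby lose their last presence are
#' removed as well. Surviving labels are preserved.
#'
#' @param m binary presence/absence matrix (units x species).
#' @return the reduced matrix, with attributes `dropped_units` and
#'   `dropped_species` naming what was removed.
#' @export
drop_empty_units <- function(m) {
  stopifnot(is.matrix(m))
  keep_u <- rowSums(m) > 0
  out <- m[keep_u, , drop = FALSE]
  keep_s <- colSums(out) > 0
  out <- out[, keep_s, drop = FALSE]
  attr(out, "dropped_units") <- rownames(m)[!keep_u]
  attr(out, "dropped_species") <- colnames(m)[!keep_s]
  attr(out, "n_unassigned") <- attr(m, "n_unassigned")
  out
}

#' Write / read a presence/absence matrix as CSV
#'
#' Units are rows (first column, named `unit_id`), species are columns.
#'
#' @param m binary matrix.
#' @param path file path.
#' @return `read_presence_absence` returns the integer matrix.
#' @export
write_presence_absence <- function(m, path) {
  df <- data.frame(unit_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_absence
#' @export
read_presence_absence <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
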