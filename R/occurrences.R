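# Occurrence ingestion, curation and summary tables.
#
# Records are plain data frames with the canonical columns
#   taxon_name, phylum, latitude, longitude, depth_m, source_id, taxon_rank
# (latitude in decimal degrees, +N; longitude +E; depth in metres, positive
# down). Input files use configurable column names; the defaults follow
# Darwin Core.

OCC_COLUMNS <- c("taxon_name", "phylum", "latitude", "longitude",
                 "depth_m", "source_id", "taxon_rank")

#' Column-name mapping for occurrence tables
#'
#' Maps the canonical record fields onto the column names found in an input
#' file. Defaults are the Darwin Core terms. Depth may come either from a
#' single column (`depth`) or from a minimum/maximum pair, in which case the
#' record depth is the midpoint of the two (a single available bound is used
#' as-is).
#'
#' @param taxon_name,phylum,latitude,longitude,source_id,taxon_rank column
#'   names in the input file. `phylum`, `source_id` and `taxon_rank` are
#'   optional: set to `NA` to skip.
#' @param depth_min,depth_max,depth depth column names; at least one of the
#'   three must be present in the file.
#' @return a named character vector usable as the `dialect` argument of
#'   [read_occurrences()].
#' @export
occurrence_dialect <- function(taxon_name = "scientificName",
                               phylum = "phylum",
                               latitude = "decimalLatitude",
                               longitude = "decimalLongitude",
                               depth_min = "minimumDepthInMeters",
                               depth_max = "maximumDepthInMeters",
                               depth = "depthInMeters",
                               source_id = "datasetID",
                               taxon_rank = "taxonRank") {
  c(taxon_name = taxon_name, phylum = phylum, latitude = latitude,
    longitude = longitude, depth_min = depth_min, depth_max = depth_max,
    depth = depth, source_id = source_id, taxon_rank = taxon_rank)
}

#' Read an occurrence table
#'
#' Reads a CSV/TSV occurrence file into the canonical record data frame.
#' Rows whose coordinates or depth cannot be parsed (missing, non-numeric,
#' or coordinates outside valid ranges) are returned in a `rejects` table
#' with a reason, never silently dropped.
#'
#' @param path path to a delimited text file. The separator is inferred from
#'   the extension (`.tsv`/`.tab` = tab, otherwise comma) unless `sep` is
#'   given.
#' @param dialect column mapping from [occurrence_dialect()].
#' @param sep optional field separator override.
#' @return a list with elements `records` (canonical data frame) and
#'   `rejects` (offending input rows plus a `reason` column).
#' @export
read_occurrences <- function(path, dialect = occurrence_dialect(), sep = NULL) {
  if (!file.exists(path)) stop_input("occurrence file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", colClasses = "character")
  if (nrow(raw) == 0)
    return(list(records = empty_records(), rejects = cbind(raw, reason = character(0))))

  mandatory <- c("taxon_name", "latitude", "longitude")
  for (field in mandatory) {
    if (!dialect[[field]] %in% names(raw))
      stop_input(sprintf("missing mandatory column '%s' (field '%s')",
                         dialect[[field]], field))
  }
  has <- function(field) !is.na(dialect[[field]]) && dialect[[field]] %in% names(raw)
  if (!has("depth") && !has("depth_min") && !has("depth_max"))
    stop_input(sprintf("missing mandatory depth column ('%s', or '%s'/'%s')",
                       dialect[["depth"]], dialect[["depth_min"]], dialect[["depth_max"]]))

  num <- function(field) {
    if (!has(field)) return(rep(NA_real_, nrow(raw)))
    suppressWarnings(as.numeric(raw[[dialect[[field]]]]))
  }
  chr <- function(field) {
    if (!has(field)) return(rep(NA_character_, nrow(raw)))
    as.character(raw[[dialect[[field]]]])
  }

  lat <- num("latitude"); lon <- num("longitude")
  dmin <- num("depth_min"); dmax <- num("depth_max"); dsingle <- num("depth")
  depth <- ifelse(!is.na(dmin) & !is.na(dmax), (dmin + dmax) / 2,
                  ifelse(!is.na(dmin), dmin,
                         ifelse(!is.na(dmax), dmax, dsingle)))

  bad_coord <- is.na(lat) | is.na(lon) | abs(lat) > 90 | abs(lon) > 180
  bad_depth <- is.na(depth)
  bad <- bad_coord | bad_depth

  records <- data.frame(
    taxon_name = chr("taxon_name"),
    phylum     = chr("phylum"),
    latitude   = lat,
    longitude  = lon,
    depth_m    = depth,
    source_id  = chr("source_id"),
    taxon_rank = chr("taxon_rank"),
    stringsAsFactors = FALSE
  )
  rejects <- cbind(raw[bad, , drop = FALSE],
                   reason = ifelse(bad_coord[bad], "unparsable coordinates",
                                   "unparsable depth"))
  rownames(records) <- rownames(rejects) <- NULL
  list(records = records[!bad, , drop = FALSE], rejects = rejects)
}

empty_records <- function() {
  out <- data.frame(taxon_name = character(0), phylum = character(0),
                    latitude = numeric(0), longitude = numeric(0),
                    depth_m = numeric(0), source_id = character(0),
                    taxon_rank = character(0), stringsAsFactors = FALSE)
  out
}

#' Curation settings
#'
#' Bundles the record-retention rules: a study-area predicate (the exclusive
#' economic zone in the motivating analysis), a depth window, the
#' species-rank requirement, and an optional local synonym map applied
#' before all filters.
#'
#' @param depth_min,depth_max retained depth window in metres (defaults
#'   200–5,000 m, the deep-water window).
#' @param study_area either a bounding box from [study_area_box()] or a
#'   predicate `function(latitude, longitude)` returning a logical vector.
#' @param require_species_rank drop records not named to species level
#'   (see [is_species_rank()]).
#' @param synonym_map optional named character vector `old name -> accepted
#'   name`, applied before filtering. Values must themselves be accepted
#'   names (no chains).
#' @return an object of class `curation_config`.
#' @export
curation_config <- function(depth_min = 200, depth_max = 5000,
                            study_area = study_area_box(),
                            require_species_rank = TRUE,
                            synonym_map = NULL) {
  assert_numeric_scalar(depth_min, "depth_min", lower = 0)
  assert_numeric_scalar(depth_max, "depth_max", lower = 0)
  if (depth_min >= depth_max) stop_input("depth_min must be < depth_max")
  if (!is.null(synonym_map)) {
    if (is.null(names(synonym_map)) || any(names(synonym_map) == ""))
      stop_input("synonym_map must be a named character vector")
    chained <- synonym_map[synonym_map %in% names(synonym_map) &
                             synonym_map != names(synonym_map)]
    if (length(chained))
      stop_input("synonym_map contains chains (a value is also a mapped old name): ",
                 paste(chained, collapse = ", "))
  }
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 study_area = study_area,
                 require_species_rank = isTRUE(require_species_rank),
                 synonym_map = synonym_map),
            class = "curation_config")
}

#' Rectangular study-area predicate
#'
#' The default box (6°N–36°S, 55°W–25°W) spans the Brazilian margin study
#' area used throughout the package; it stands in for the exact exclusive
#' economic zone boundary, which users can replace with their own polygon
#' predicate.
#'
#' @param lat_max,lat_min,lon_min,lon_max box edges in decimal degrees.
#' @return a predicate `function(latitude, longitude)`.
#' @export
study_area_box <- function(lat_max = 6, lat_min = -36,
                           lon_min = -55, lon_max = -25) {
  if (lat_min >= lat_max || lon_min >= lon_max)
    stop_input("degenerate study-area box")
  function(latitude, longitude) {
    latitude >= lat_min & latitude <= lat_max &
      longitude >= lon_min & longitude <= lon_max
  }
}

#' Is a taxon name at species rank?
#'
#' A name counts as species-rank when it has at least two whitespace-
#' separated epithets and does not end in an open-nomenclature marker
#' ("sp.", "spp.", "cf."). This is a purely lexical rule; no taxonomy
#' service is consulted.
#'
#' @param name character vector of scientific names.
#' @return logical vector.
#' @export
is_species_rank <- function(name) {
  name <- trimws(as.character(name))
  out <- logical(length(name))
  ok <- !is.na(name) & nzchar(name)
  toks <- strsplit(name[ok], "\\s+")
  out[ok] <- vapply(toks, function(tk) {
    length(tk) >= 2 &&
      !grepl("^(sp|spp|cf)\\.?$", tk[length(tk)], ignore.case = TRUE)
  }, logical(1))
  out
}

#' Curate occurrence records
#'
#' Applies the synonym map, then removes records outside the study area,
#' outside the depth window, or (optionally) not identified to species
#' level. Filtering never fails on content; every removal is tallied in the
#' returned report, which always balances
#' (`n_input = n_retained + sum(n_removed_by_rule)`).
#'
#' @param records canonical occurrence data frame (see [read_occurrences()]).
#' @param config a [curation_config()].
#' @return list with `records` (retained rows) and `report` (class
#'   `curation_report`: `n_input`, `n_removed_by_rule`, `n_retained`).
#' @export
curate <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  records <- as_records(records)
  n_input <- nrow(records)
  if (!is.null(config$synonym_map)) {
    hit <- records$taxon_name %in% names(config$synonym_map)
    records$taxon_name[hit] <- unname(config$synonym_map[records$taxon_name[hit]])
  }

  area <- config$study_area
  if (!is.function(area)) stop_input("study_area must be a predicate function")

  unparsable <- is.na(records$latitude) | is.na(records$longitude) |
    is.na(records$depth_m)
  in_area <- !unparsable & area(records$latitude, records$longitude)
  in_depth <- !unparsable & records$depth_m >= config$depth_min &
    records$depth_m <= config$depth_max
  sp_rank <- if (config$require_species_rank) is_species_rank(records$taxon_name)
             else rep(TRUE, n_input)

  # each removed record is attributed to the first failing rule, in the
  # order: unparsable, out-of-area, out-of-depth, not-species-rank
  rule <- rep(NA_character_, n_input)
  rule[!sp_rank] <- "not_species_rank"
  rule[!in_depth] <- "out_of_depth"
  rule[!in_area] <- "out_of_area"
  rule[unparsable] <- "unparsable"
  keep <- is.na(rule)

  counts <- c(out_of_area = sum(rule == "out_of_area", na.rm = TRUE),
              out_of_depth = sum(rule == "out_of_depth", na.rm = TRUE),
              not_species_rank = sum(rule == "not_species_rank", na.rm = TRUE),
              unparsable = sum(rule == "unparsable", na.rm = TRUE))
  report <- structure(list(n_input = n_input,
                           n_removed_by_rule = as.list(counts),
                           n_retained = sum(keep)),
                      class = "curation_report")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

as_records <- function(records) {
  if (is.list(records) && !is.data.frame(records) && !is.null(records$records))
    records <- records$records
  if (!is.data.frame(records)) stop_input("records must be a data frame")
  missing_cols <- setdiff(c("taxon_name", "latitude", "longitude", "depth_m"),
                          names(records))
  if (length(missing_cols))
    stop_input("records lack columns: ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(OCC_COLUMNS, names(records))) records[[col]] <- NA
  records[OCC_COLUMNS]
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report:", x$n_input, "records in,", x$n_retained, "retained\n")
  for (r in names(x$n_removed_by_rule))
    cat(sprintf("  removed (%s): %d\n", r, x$n_removed_by_rule[[r]]))
  invisible(x)
}

#' Summarize occurrences and species by phylum and latitudinal region
#'
#' Counts occurrence records and distinct species per phylum in the tropical
#' (latitude above `split_latitude`) and subtropical (at or below it)
#' portions of the study area. The default split, 21°S, is the
#' Vitória–Trindade Ridge, the natural boundary between the tropical and
#' subtropical margin. Marginal totals per region are appended as phylum
#' `"Total"` (species totals count distinct names within the region).
#'
#' @param records curated occurrence data frame.
#' @param split_latitude tropical/subtropical boundary in decimal degrees.
#' @return data frame with columns `phylum`, `region`, `n_occurrences`,
#'   `n_species`.
#' @export
summarize_by_phylum_region <- function(records, split_latitude = -21) {
  records <- as_records(records)
  region <- ifelse(records$latitude > split_latitude, "tropical", "subtropical")
  phylum <- ifelse(is.na(records$phylum), "(unknown)", records$phylum)
  phyla <- sort(unique(phylum))
  regions <- c("tropical", "subtropical")
  rows <- list()
  for (p in phyla) for (r in regions) {
    sel <- phylum == p & region == r
    rows[[length(rows) + 1L]] <- data.frame(
      phylum = p, region = r,
      n_occurrences = sum(sel),
      n_species = length(unique(records$taxon_name[sel])),
      stringsAsFactors = FALSE)
  }
  for (r in regions) {
    sel <- region == r
    rows[[length(rows) + 1L]] <- data.frame(
      phylum = "Total", region = r,
      n_occurrences = sum(sel),
      n_species = length(unique(records$taxon_name[sel])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load the packaged phylum-by-region reference table
#'
#' The packaged fixture tallies curated deep-sea benthic occurrences and
#' species per phylum in the tropical and subtropical Brazilian margin
#' (10 phyla, 4,167 occurrences in total).
#'
#' @return data frame with columns `phylum`, `region`, `n_occurrences`,
#'   `n_species`.
#' @export
phylum_region_table <- function() {
  path <- system.file("extdata", "table1_phylum_region.csv",
                      package = "deepbioreg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Expand a phylum-by-region tally into pseudo-records
#'
#' Inverse of [summarize_by_phylum_region()] up to identity of the species:
#' for each (phylum, region) cell it fabricates `n_species` distinct
#' species-rank names and distributes `n_occurrences` records among them
#' (each species at least once). Tropical rows are placed north of the
#' split latitude, subtropical rows south of it, inside the default study
#' area and depth window, so the pseudo-records survive default curation
#' and re-summarize to the input table exactly.
#'
#' @param tab data frame with columns `phylum`, `region`, `n_occurrences`,
#'   `n_species` (marginal `"Total"` rows are ignored).
#' @param split_latitude boundary used to place the two regions.
#' @return canonical occurrence data frame.
#' @export
expand_phylum_region_table <- function(tab, split_latitude = -21) {
  stopifnot(all(c("phylum", "region", "n_occurrences", "n_species") %in% names(tab)))
  tab <- tab[tab$phylum != "Total", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tab))) {
    n_occ <- tab$n_occurrences[i]; n_sp <- tab$n_species[i]
    if (n_occ == 0) next
    if (n_sp < 1 || n_sp > n_occ)
      stop_input("cell has more species than occurrences: row ", i)
    genus <- gsub("[^A-Za-z]", "", tab$phylum[i])
    sp_names <- sprintf("%s %sensis%03d", genus,
                        substr(tab$region[i], 1, 4), seq_len(n_sp))
    # species j gets one record; the remainder all go to species 1
    taxon <- c(sp_names, rep(sp_names[1], n_occ - n_sp))
    lat <- if (tab$region[i] == "tropical") split_latitude + 5 else split_latitude - 5
    out[[length(out) + 1L]] <- data.frame(
      taxon_name = taxon, phylum = tab$phylum[i],
      latitude = lat, longitude = -38, depth_m = 500,
      source_id = "table-replay", taxon_rank = "Species",
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty_records()
  rownames(res) <- NULL
  res
}

#' Write a curation report as JSON
#'
#' @param report a `curation_report`.
#' @param path output file.
#' @export
write_curation_report <- function(report, path) {
  stopifnot(inherits(report, "curation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
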