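# Synthetic occurrence data with known regional structure.
#
# Each unit's assemblage is built from three pools: species unique to the
# unit, species shared by every unit of its group, and cosmopolitan species
# shared by all units. With u, w, g the three counts, the expected Simpson
# turnover is u / (u + w + g) within a group and (u + w) / (u + w + g)
# across groups — so planted partitions come with an analytic truth matrix
# against which the whole pipeline can be checked. Records then emulate
# field sampling: uniform species picks (the analysis is presence-based, so
# no abundance model) at coordinates uniform inside each unit's geometry,
# with per-unit record counts free to vary to emulate effort imbalance.

#' Configuration for the synthetic assemblage generator
#'
#' @param planted_partition named list of character vectors: group name ->
#'   unit ids. Every unit belongs to exactly one group.
#' @param species_per_unit_unique species found only in that unit (u).
#' @param species_shared_within_group species shared by all units of a
#'   group, absent elsewhere (w).
#' @param species_shared_across_groups cosmopolitan species present in
#'   every unit (g).
#' @param records_per_unit records to draw per unit; a scalar, or a named
#'   vector (unit id -> count) to emulate unequal sampling effort.
#' @param unit_geometries optional data frame (`unit_id`, `lat_north`,
#'   `lat_south`, `lon_west`, `lon_east`, `depth_min`, `depth_max`) placing
#'   each unit; defaults to [default_unit_geometries()] over the units.
#' @param seed master seed for record sampling.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(planted_partition = list(G1 = c("U1", "U2", "U3"),
                                                      G2 = c("U4", "U5", "U6")),
                             species_per_unit_unique = 5,
                             species_shared_within_group = 5,
                             species_shared_across_groups = 0,
                             records_per_unit = 50,
                             unit_geometries = NULL,
                             seed = 1) {
  units <- unlist(planted_partition, use.names = FALSE)
  if (anyDuplicated(units))
    stop_input("a unit may belong to only one group")
  for (nm in c("species_per_unit_unique", "species_shared_within_group",
               "species_shared_across_groups"))
    assert_numeric_scalar(get(nm), nm, lower = 0)
  if (is.null(unit_geometries)) unit_geometries <- default_unit_geometries(units)
  stopifnot(all(units %in% unit_geometries$unit_id))
  if (is.null(names(records_per_unit)))
    records_per_unit <- structure(rep_len(records_per_unit, length(units)),
                                  names = units)
  structure(list(planted_partition = planted_partition,
                 u = as.integer(species_per_unit_unique),
                 w = as.integer(species_shared_within_group),
                 g = as.integer(species_shared_across_groups),
                 records_per_unit = records_per_unit,
                 unit_geometries = unit_geometries,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default synthetic unit geometries
#'
#' Tiles the study-area box with one latitude slice per unit, all at
#' upper-bathyal depths (250–750 m) and mid-margin longitudes, so every
#' synthetic record passes default curation and the units can be mapped
#' onto band-based schemes.
#'
#' @param unit_ids character vector of unit ids.
#' @return geometry data frame (see [synthetic_config()]).
#' @export
default_unit_geometries <- function(unit_ids) {
  n <- length(unit_ids)
  edges <- seq(5, -34, length.out = n + 1)
  data.frame(unit_id = unit_ids,
             lat_north = edges[-(n + 1)], lat_south = edges[-1],
             lon_west = -45, lon_east = -30,
             depth_min = 250, depth_max = 750,
             stringsAsFactors = FALSE)
}

#' Generate assemblages with planted group structure
#'
#' Deterministically builds each unit's species set (unique + within-group
#' + cosmopolitan pools) and the analytic expected Simpson matrix.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `synthetic_truth`: `assemblages` (named list of
#'   species vectors), `expected_simpson` (unit x unit matrix), `partition`
#'   (named group vector) and `cfg`.
#' @export
generate_assemblages <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  units <- unlist(cfg$planted_partition, use.names = FALSE)
  group_of <- rep(names(cfg$planted_partition),
                  lengths(cfg$planted_partition))
  names(group_of) <- units
  cosmo <- if (cfg$g > 0) sprintf("Cosmopolites communis%02d", seq_len(cfg$g))
           else character(0)
  assemblages <- lapply(units, function(uid) {
    grp <- group_of[[uid]]
    uniq <- if (cfg$u > 0)
      sprintf("Endemicus %s%02d", tolower(uid), seq_len(cfg$u)) else character(0)
    shared <- if (cfg$w > 0)
      sprintf("Regionalis %s%02d", tolower(grp), seq_len(cfg$w)) else character(0)
    c(uniq, shared, cosmo)
  })
  names(assemblages) <- units
  tot <- cfg$u + cfg$w + cfg$g
  if (tot == 0) stop_input("all species pools are empty")
  n <- length(units)
  expected <- matrix(0, n, n, dimnames = list(units, units))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    expected[i, j] <- if (group_of[[units[i]]] == group_of[[units[j]]])
      cfg$u / tot else (cfg$u + cfg$w) / tot
  }
  structure(list(assemblages = assemblages, expected_simpson = expected,
                 partition = group_of, cfg = cfg),
            class = "synthetic_truth")
}

#' Draw occurrence records from a synthetic truth
#'
#' For each unit, `records_per_unit` records are drawn: the species uniform
#' over the unit's assemblage, coordinates and depth uniform inside the
#' unit's geometry. Completeness (every species drawn at least once) is not
#' guaranteed at low effort — check with [assemblage_completeness()]
#' before comparing a rebuilt matrix against the truth.
#'
#' @param cfg a [synthetic_config()].
#' @param truth the matching [generate_assemblages()] output (regenerated
#'   from `cfg` when omitted).
#' @return canonical occurrence data frame (the same dialect
#'   [read_occurrences()] produces).
#' @export
generate_records <- function(cfg, truth = generate_assemblages(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "synthetic_truth"))
  units <- names(truth$assemblages)
  seeds <- derive_seeds(cfg$seed, "records", length(units))
  geo <- cfg$unit_geometries
  out <- lapply(seq_along(units), function(i) {
    uid <- units[i]
    n_r <- cfg$records_per_unit[[uid]]
    if (n_r == 0) return(NULL)
    g <- geo[geo$unit_id == uid, , drop = FALSE]
    set.seed(seeds[i])
    pool <- truth$assemblages[[uid]]
    data.frame(taxon_name = pool[sample.int(length(pool), n_r, replace = TRUE)],
               phylum = "Synthetica",
               latitude = stats::runif(n_r, g$lat_south, g$lat_north),
               longitude = stats::runif(n_r, g$lon_west, g$lon_east),
               depth_m = stats::runif(n_r, g$depth_min, g$depth_max),
               source_id = "synthetic",
               taxon_rank = "Species",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_records()
  rownames(res) <- NULL
  res
}

#' Check sampling completeness of synthetic records
#'
#' @param records output of [generate_records()].
#' @param truth the matching `synthetic_truth`.
#' @return data frame per unit: expected and observed species counts and a
#'   `complete` flag (records are located by their unit's geometry).
#' @export
assemblage_completeness <- function(records, truth) {
  geo <- truth$cfg$unit_geometries
  units <- names(truth$assemblages)
  rows <- lapply(units, function(uid) {
    g <- geo[geo$unit_id == uid, , drop = FALSE]
    sel <- records$latitude <= g$lat_north & records$latitude >= g$lat_south &
      records$depth_m >= g$depth_min & records$depth_m <= g$depth_max
    seen <- unique(records$taxon_name[sel])
    expected <- truth$assemblages[[uid]]
    data.frame(unit_id = uid, n_species_expected = length(expected),
               n_species_observed = sum(expected %in% seen),
               complete = all(expected %in% seen), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign synthetic records to their generating units
#'
#' Convenience assignment function for [build_presence_absence()] when the
#' analysis works directly on the planted units rather than a packaged
#' scheme: each record maps to the unit whose geometry contains it.
#'
#' @param truth a `synthetic_truth`.
#' @return `function(records) -> character vector of unit ids`.
#' @export
synthetic_assigner <- function(truth) {
  geo <- truth$cfg$unit_geometries
  function(records) {
    out <- rep(NA_character_, nrow(records))
    for (i in seq_len(nrow(geo))) {
      hit <- records$latitude <= geo$lat_north[i] &
        records$latitude >= geo$lat_south[i] &
        records$depth_m >= geo$depth_min[i] &
        records$depth_m <= geo$depth_max[i]
      out[hit & is.na(out)] <- geo$unit_id[i]
    }
    out
  }
}

#' Write synthetic truth as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path output file.
#' @export
write_synthetic_truth <- function(truth, path) {
  payload <- list(partition = as.list(truth$partition),
                  assemblages = truth$assemblages,
                  expected_simpson = truth$expected_simpson,
                  pools = list(unique = truth$cfg$u, within_group = truth$cfg$w,
                               cosmopolitan = truth$cfg$g))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}
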