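# Biogeographical classification schemes for the Brazilian continental
# margin: latitude-band x depth-stratum units with a deterministic
# point-in-unit assignment rule.
#
# Boundary conventions (shared by all constructors):
#   * depth: a stratum covers (lower, upper]; the shallowest stratum of a
#     scheme additionally includes its own lower bound, so the 200 m floor
#     is retained. This matches printed bands of the 200-800 / 801-3500
#     style with no gap at integer boundaries.
#   * latitude: a band covers (south, north]; the southernmost band of a
#     scheme additionally includes its own southern limit.
#   * longitude participates only through optional polygon predicates (not
#     part of the packaged defaults, which are latitude-only bands).

new_scheme <- function(scheme_id, units) {
  stopifnot(is.data.frame(units),
            all(c("unit_id", "display_name", "stratum",
                  "depth_lower", "depth_upper",
                  "lat_north", "lat_south") %in% names(units)))
  if (anyDuplicated(units$unit_id))
    stop_input("duplicate unit_id in scheme ", scheme_id)
  if (any(units$depth_lower >= units$depth_upper))
    stop_input("configuration error: unit with depth_lower >= depth_upper")
  if (any(units$lat_south >= units$lat_north))
    stop_input("configuration error: unit with lat_south >= lat_north")
  # no two units may overlap jointly in depth and latitude (half-open
  # (lower, upper] intervals: overlap iff max(lowers) < min(uppers))
  n <- nrow(units)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      depth_olap <- max(units$depth_lower[c(i, j)]) <
        min(units$depth_upper[c(i, j)]) - 1e-9
      lat_olap <- max(units$lat_south[c(i, j)]) <
        min(units$lat_north[c(i, j)]) - 1e-9
      if (depth_olap && lat_olap)
        stop_input("configuration error: units ", units$unit_id[i], " and ",
                   units$unit_id[j], " overlap")
    }
  }
  rownames(units) <- NULL
  structure(list(scheme_id = scheme_id, units = units), class = "biogeo_scheme")
}

#' @export
print.biogeo_scheme <- function(x, ...) {
  cat(sprintf("Biogeographical scheme '%s' (%d units)\n",
              x$scheme_id, nrow(x$units)))
  print(x$units, row.names = FALSE)
  invisible(x)
}

#' Number of units in a scheme
#'
#' @param scheme a `biogeo_scheme`.
#' @param stratum optional stratum name(s) to count within; `"bathyal"`
#'   counts every unit whose depth range lies inside 200–3,500 m.
#' @return integer count.
#' @export
n_units <- function(scheme, stratum = NULL) {
  stopifnot(inherits(scheme, "biogeo_scheme"))
  u <- scheme$units
  if (is.null(stratum)) return(nrow(u))
  if (identical(stratum, "bathyal"))
    return(sum(u$depth_lower >= 200 - 1e-9 & u$depth_upper <= 3500 + 1e-9))
  sum(u$stratum %in% stratum)
}

unit_row <- function(unit_id, display_name, stratum, depth_lower, depth_upper,
                     lat_north, lat_south) {
  data.frame(unit_id = unit_id, display_name = display_name, stratum = stratum,
             depth_lower = depth_lower, depth_upper = depth_upper,
             lat_north = lat_north, lat_south = lat_south,
             stringsAsFactors = FALSE)
}

abyssal_units <- function(prefix = "", lat_north, lat_south,
                          splits = c(-5, -30)) {
  if (length(splits) != 2 || splits[1] <= splits[2] ||
      splits[1] >= lat_north || splits[2] <= lat_south)
    stop_input("configuration error: abyssal splits must satisfy ",
               "lat_south < split2 < split1 < lat_north")
  rbind(
    unit_row(paste0(prefix, "AB2"), "Abyssal North Atlantic", "abyssal",
             3500, 6500, lat_north, splits[1]),
    unit_row(paste0(prefix, "AB3"), "Abyssal Brazil Basin", "abyssal",
             3500, 6500, splits[1], splits[2]),
    unit_row(paste0(prefix, "AB5"), "Abyssal Argentine Basin", "abyssal",
             3500, 6500, splits[2], lat_south))
}

#' Depth-province scheme (scheme 1)
#'
#' Seven units: two upper-bathyal provinces (UBNA, UBSA; 200–800 m), two
#' lower-bathyal provinces (LBNA, LBSA; 800–3,500 m) split at the
#' north/south boundary, and three abyssal provinces (AB2 North Atlantic,
#' AB3 Brazil Basin, AB5 Argentine Basin; 3,500–6,500 m).
#'
#' @param north_boundary latitude separating the North and South bathyal
#'   provinces (default 5°S).
#' @param lat_north,lat_south scheme extent in decimal degrees.
#' @param abyssal_splits two latitudes separating AB2/AB3 and AB3/AB5
#'   (defaults 5°S and 30°S, the Rio Grande Rise; the exact published
#'   province boundaries are not reproduced here).
#' @return a `biogeo_scheme`.
#' @export
make_watling_scheme <- function(north_boundary = -5, lat_north = 6,
                                lat_south = -35, abyssal_splits = c(-5, -30)) {
  if (north_boundary >= lat_north || north_boundary <= lat_south)
    stop_input("configuration error: north_boundary outside scheme extent")
  units <- rbind(
    unit_row("UBNA", "Upper Bathyal North Atlantic", "upper_bathyal",
             200, 800, lat_north, north_boundary),
    unit_row("UBSA", "Upper Bathyal South Atlantic", "upper_bathyal",
             200, 800, north_boundary, lat_south),
    unit_row("LBNA", "Lower Bathyal North Atlantic", "lower_bathyal",
             800, 3500, lat_north, north_boundary),
    unit_row("LBSA", "Lower Bathyal South Atlantic", "lower_bathyal",
             800, 3500, north_boundary, lat_south),
    abyssal_units("", lat_north, lat_south, abyssal_splits))
  new_scheme("watling", units)
}

#' Hybrid ecoregion-by-depth scheme (scheme 2)
#'
#' Ten units: the five marine-ecoregion bands at upper-bathyal depth
#' (200–800 m) — Amazonia, Northeastern, Eastern, Southeastern, Rio Grande —
#' plus the lower-bathyal (LBNA/LBSA) and abyssal (AB2/AB3/AB5) provinces of
#' the depth-province scheme.
#'
#' @param ecoregion_bands named numeric vector of band boundaries from north
#'   to south; `length(ecoregion_bands) = n ecoregions + 1`. The default
#'   bands (6°N, 2°S, 13°S, 21°S, 28°S, 35°S) are latitude-only stand-ins
#'   for the published coastal ecoregion polygons, preserving their order
#'   and the 21°S ridge boundary.
#' @inheritParams make_watling_scheme
#' @return a `biogeo_scheme`.
#' @export
make_hybrid_scheme <- function(ecoregion_bands = c(Amazonia = 6, Northeastern = -2,
                                                   Eastern = -13, Southeastern = -21,
                                                   RioGrande = -28, .south = -35),
                               north_boundary = -5, abyssal_splits = c(-5, -30)) {
  if (is.unsorted(rev(ecoregion_bands), strictly = TRUE))
    stop_input("configuration error: ecoregion_bands must strictly decrease")
  n_eco <- length(ecoregion_bands) - 1L
  eco_names <- names(ecoregion_bands)[seq_len(n_eco)]
  eco <- do.call(rbind, lapply(seq_len(n_eco), function(i) {
    unit_row(paste0("UB_", eco_names[i]),
             paste("Upper bathyal", eco_names[i]), "upper_bathyal",
             200, 800, ecoregion_bands[[i]], ecoregion_bands[[i + 1L]])
  }))
  lat_north <- ecoregion_bands[[1]]
  lat_south <- ecoregion_bands[[length(ecoregion_bands)]]
  units <- rbind(
    eco,
    unit_row("LBNA", "Lower Bathyal North Atlantic", "lower_bathyal",
             800, 3500, lat_north, north_boundary),
    unit_row("LBSA", "Lower Bathyal South Atlantic", "lower_bathyal",
             800, 3500, north_boundary, lat_south),
    abyssal_units("", lat_north, lat_south, abyssal_splits))
  new_scheme("hybrid", units)
}

#' Default water-mass depth envelopes
#'
#' Depth envelopes (m) of the bathyal water masses per region. The tropical
#' column (North, East regions) holds SACW, AAIW and NADW; the subtropical
#' (South) column additionally holds UCPW between AAIW and NADW, consistent
#' with the permanent pycnocline at 1,000–1,300 m above the NADW. Envelopes
#' within one region must tile 200–3,500 m without gaps or overlaps. The
#' exact numeric limits per region are oceanographic stand-ins and fully
#' configurable.
#'
#' @return named list of per-region data frames (`water_mass`, `lower`,
#'   `upper`).
#' @export
default_watermass_envelopes <- function() {
  ne <- data.frame(water_mass = c("SACW", "AAIW", "NADW"),
                   lower = c(200, 600, 1200), upper = c(600, 1200, 3500),
                   stringsAsFactors = FALSE)
  s <- data.frame(water_mass = c("SACW", "AAIW", "UCPW", "NADW"),
                  lower = c(200, 600, 1000, 1300),
                  upper = c(600, 1000, 1300, 3500),
                  stringsAsFactors = FALSE)
  list(North = ne, East = ne, South = s)
}

#' Water-mass by region scheme (scheme 3)
#'
#' The bathyal column (200–3,500 m) of each of three latitudinal regions —
#' North (4°N–5°S), East (5°S–21°S), South (21°S–35°S) — is divided into its
#' water masses: SACW, AAIW and NADW everywhere, plus UCPW in the South
#' only (10 bathyal units). The abyssal zone is Antarctic Bottom Water
#' everywhere and keeps the three abyssal provinces (AABW_AB2, AABW_AB3,
#' AABW_AB5).
#'
#' @param envelopes per-region water-mass envelopes as produced by
#'   [default_watermass_envelopes()]. Envelopes must tile each region's
#'   200–3,500 m column exactly; UCPW is only admitted in the South region.
#' @param region_limits four latitudes bounding the North/East/South
#'   regions from north to south (default 4°N, 5°S, 21°S, 35°S).
#' @param abyssal_splits as in [make_watling_scheme()].
#' @return a `biogeo_scheme`.
#' @export
make_watermass_scheme <- function(envelopes = default_watermass_envelopes(),
                                  region_limits = c(4, -5, -21, -35),
                                  abyssal_splits = c(-5, -30)) {
  if (length(region_limits) != 4 || is.unsorted(rev(region_limits), strictly = TRUE))
    stop_input("configuration error: region_limits must be 4 strictly decreasing latitudes")
  regions <- c("North", "East", "South")
  if (!setequal(names(envelopes), regions))
    stop_input("configuration error: envelopes must be named North, East, South")
  known <- c("SACW", "AAIW", "UCPW", "NADW")
  units <- NULL
  for (i in seq_along(regions)) {
    reg <- regions[i]
    env <- envelopes[[reg]]
    if (!all(env$water_mass %in% known))
      stop_input("configuration error: unknown water mass in region ", reg)
    if ("UCPW" %in% env$water_mass && reg != "South")
      stop_input("configuration error: UCPW is absent from the tropical (",
                 reg, ") water column")
    env <- env[order(env$lower), , drop = FALSE]
    if (env$lower[1] != 200 || env$upper[nrow(env)] != 3500 ||
        (nrow(env) > 1 && any(abs(env$lower[-1] - env$upper[-nrow(env)]) > 1e-9)))
      stop_input("configuration error: envelopes in region ", reg,
                 " must tile 200-3500 m without gaps or overlaps")
    suffix <- substr(reg, 1, 1)
    units <- rbind(units, do.call(rbind, lapply(seq_len(nrow(env)), function(k) {
      unit_row(paste0(env$water_mass[k], "_", suffix),
               paste(env$water_mass[k], reg, "region"), "bathyal",
               env$lower[k], env$upper[k],
               region_limits[i], region_limits[i + 1L])
    })))
  }
  units <- rbind(units, abyssal_units("AABW_", region_limits[1],
                                      region_limits[4], abyssal_splits))
  new_scheme("watermass", units)
}

#' Consolidated proposal scheme
#'
#' The synthesis the three tested schemes point to: four upper-bathyal
#' ecoregions (Amazonia, Northeastern, Eastern, Southern; 200–1,000 m),
#' three lower-bathyal ecoregions (North, East, South; 1,000–3,500 m) —
#' seven bathyal ecoregions in all — plus the three abyssal provinces.
#'
#' @param upper_bands named boundaries of the upper-bathyal ecoregions,
#'   north to south (default 6°N, 2°S, 13°S, 21°S, 35°S).
#' @param region_limits lower-bathyal region boundaries (default 4°N, 5°S,
#'   21°S, 35°S).
#' @param abyssal_splits as in [make_watling_scheme()].
#' @return a `biogeo_scheme`.
#' @export
make_proposed_scheme <- function(upper_bands = c(Amazonia = 6, Northeastern = -2,
                                                 Eastern = -13, Southern = -21,
                                                 .south = -35),
                                 region_limits = c(4, -5, -21, -35),
                                 abyssal_splits = c(-5, -30)) {
  if (is.unsorted(rev(upper_bands), strictly = TRUE))
    stop_input("configuration error: upper_bands must strictly decrease")
  if (length(region_limits) != 4 || is.unsorted(rev(region_limits), strictly = TRUE))
    stop_input("configuration error: region_limits must be 4 strictly decreasing latitudes")
  n_ub <- length(upper_bands) - 1L
  ub_names <- names(upper_bands)[seq_len(n_ub)]
  ub <- do.call(rbind, lapply(seq_len(n_ub), function(i) {
    unit_row(paste0("UB_", ub_names[i]),
             paste("Upper bathyal", ub_names[i]), "upper_bathyal",
             200, 1000, upper_bands[[i]], upper_bands[[i + 1L]])
  }))
  lb_names <- c("North", "East", "South")
  lb <- do.call(rbind, lapply(1:3, function(i) {
    unit_row(paste0("LB_", lb_names[i]),
             paste("Lower bathyal", lb_names[i]), "lower_bathyal",
             1000, 3500, region_limits[i], region_limits[i + 1L])
  }))
  units <- rbind(ub, lb,
                 abyssal_units("", upper_bands[[1]],
                               upper_bands[[length(upper_bands)]], abyssal_splits))
  new_scheme("proposed", units)
}

#' Construct a scheme by name
#'
#' @param name one of `"watling"`, `"hybrid"`, `"watermass"`, `"proposed"`.
#' @param ... overrides passed to the constructor.
#' @return a `biogeo_scheme`.
#' @export
make_scheme <- function(name, ...) {
  switch(match.arg(name, c("watling", "hybrid", "watermass", "proposed")),
         watling = make_watling_scheme(...),
         hybrid = make_hybrid_scheme(...),
         watermass = make_watermass_scheme(...),
         proposed = make_proposed_scheme(...))
}

#' Assign occurrence records to biogeographical units
#'
#' Deterministic point-in-unit assignment: a record belongs to a unit when
#' its depth lies in the unit's stratum (`(lower, upper]`, the scheme's
#' shallowest floor included) and its latitude in the unit's band
#' (`(south, north]`, the scheme's southernmost limit included). Records
#' matching no unit get `NA`. Matching two units is a scheme-configuration
#' bug and raises an error.
#'
#' @param records canonical occurrence data frame (or a single record as a
#'   one-row data frame).
#' @param scheme a `biogeo_scheme`.
#' @return character vector of unit ids, `NA` where unassigned.
#' @export
assign_units <- function(records, scheme) {
  stopifnot(inherits(scheme, "biogeo_scheme"))
  records <- as_records(records)
  u <- scheme$units
  depth_floor <- min(u$depth_lower)
  lat_floor <- min(u$lat_south)
  out <- rep(NA_character_, nrow(records))
  if (!nrow(records)) return(out)
  hit_count <- integer(nrow(records))
  for (k in seq_len(nrow(u))) {
    in_depth <- (records$depth_m > u$depth_lower[k] |
                   (u$depth_lower[k] == depth_floor &
                      records$depth_m == depth_floor)) &
      records$depth_m <= u$depth_upper[k]
    in_lat <- (records$latitude > u$lat_south[k] |
                 (u$lat_south[k] == lat_floor &
                    records$latitude == lat_floor)) &
      records$latitude <= u$lat_north[k]
    hit <- !is.na(in_depth) & !is.na(in_lat) & in_depth & in_lat
    hit_count[hit] <- hit_count[hit] + 1L
    out[hit] <- u$unit_id[k]
  }
  if (any(hit_count > 1L))
    stop_input("configuration error: a record matches more than one unit in scheme ",
               scheme$scheme_id)
  out
}

#' Write record-to-unit assignments as CSV
#'
#' @param records canonical occurrence data frame.
#' @param scheme a `biogeo_scheme`.
#' @param path output file.
#' @return the assignment data frame, invisibly.
#' @export
write_assignments <- function(records, scheme, path) {
  records <- as_records(records)
  df <- data.frame(record_id = seq_len(nrow(records)),
                   taxon_name = records$taxon_name,
                   scheme_id = scheme$scheme_id,
                   unit_id = assign_units(records, scheme),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}
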