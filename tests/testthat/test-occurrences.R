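write_occ_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

test_that("reading parses rows, applies the depth-midpoint rule, and rejects bad rows", {
  p <- write_occ_csv(c(
    "scientificName,phylum,decimalLatitude,decimalLongitude,minimumDepthInMeters,maximumDepthInMeters,datasetID",
    "Lophelia pertusa,Cnidaria,-20.5,-38.2,400,600,obis1",
    "Madrepora oculata,Cnidaria,-21.0,-39.0,800,,obis1",
    "Acanella arbuscula,Cnidaria,not-a-number,-39.0,500,500,obis1"))
  got <- read_occurrences(p)
  expect_equal(nrow(got$records), 2)
  expect_equal(got$records$depth_m, c(500, 800))  # midpoint; single bound as-is
  expect_equal(nrow(got$rejects), 1)
  expect_match(got$rejects$reason, "coordinates")

  one <- read_occurrences(write_occ_csv(c(
    "scientificName,decimalLatitude,decimalLongitude,depthInMeters",
    "Lophelia pertusa,-20,-38,350")))
  expect_equal(nrow(one$records), 1)
  expect_equal(nrow(one$rejects), 0)
})

test_that("a missing mandatory column is a format error naming the column", {
  p <- write_occ_csv(c("scientificName,decimalLongitude,depthInMeters",
                       "Lophelia pertusa,-38,350"))
  expect_error(read_occurrences(p), "decimalLatitude")
  p2 <- write_occ_csv(c("scientificName,decimalLatitude,decimalLongitude",
                        "Lophelia pertusa,-20,-38"))
  expect_error(read_occurrences(p2), "depth")
})

test_that("an empty file yields an empty record set, not an error", {
  p <- write_occ_csv("scientificName,decimalLatitude,decimalLongitude,depthInMeters")
  got <- read_occurrences(p)
  expect_equal(nrow(got$records), 0)
  expect_equal(nrow(got$rejects), 0)
})

test_that("curation filters by depth window, study area and species rank", {
  recs <- rbind(
    rec("Lophelia pertusa", depth = 150),          # too shallow
    rec("Lophelia pertusa", depth = 5500),         # too deep
    rec("Lophelia pertusa", depth = 200),          # boundary: retained
    rec("Aplysina sp.", depth = 500),              # genus-level only
    rec("Lophelia pertusa", lat = 10, depth = 500),# outside study box
    rec("Lophelia pertusa", depth = 500))          # retained
  out <- curate(recs)
  expect_equal(out$report$n_retained, 2)
  expect_equal(out$report$n_removed_by_rule$out_of_depth, 2)
  expect_equal(out$report$n_removed_by_rule$not_species_rank, 1)
  expect_equal(out$report$n_removed_by_rule$out_of_area, 1)
  expect_equal(sort(out$records$depth_m), c(200, 500))
})

test_that("species-rank detection is lexical: binomials pass, open nomenclature fails", {
  expect_equal(is_species_rank(c("Lophelia pertusa", "Aplysina sp.",
                                 "Ophiomisidium spp.", "Deltocyathus cf.",
                                 "Genusonly", "Genus cf. species", NA, "")),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("the synonym map is applied before filtering and rejects chains", {
  syn <- c("Lophelia pertusa" = "Desmophyllum pertusum")
  out <- curate(rec("Lophelia pertusa"), curation_config(synonym_map = syn))
  expect_equal(out$records$taxon_name, "Desmophyllum pertusum")
  expect_error(curation_config(synonym_map = c(a = "b", b = "c")), "chain")
})

test_that("curation balances and is order-independent", {
  set.seed(7)
  recs <- rec(sample(c("Lophelia pertusa", "Aplysina sp.", "Madrepora oculata"),
                     60, replace = TRUE),
              lat = runif(60, -40, 10), depth = runif(60, 0, 6000))
  out <- curate(recs)
  expect_equal(out$report$n_input,
               out$report$n_retained + sum(unlist(out$report$n_removed_by_rule)))
  perm <- sample.int(nrow(recs))
  out2 <- curate(recs[perm, ])
  expect_equal(out2$report, out$report)
  key <- function(df) sort(do.call(paste, df))
  expect_equal(key(out2$records), key(out$records))
})

test_that("empty input curates to an empty set with an all-zero report", {
  out <- curate(rec()[0, ])
  expect_equal(nrow(out$records), 0)
  expect_equal(out$report$n_input, 0)
  expect_true(all(unlist(out$report$n_removed_by_rule) == 0))
})

test_that("phylum/region summary counts occurrences and distinct species", {
  one <- summarize_by_phylum_region(rec("Lophelia pertusa", lat = -10))
  cell <- one[one$phylum == "Testa" & one$region == "tropical", ]
  expect_equal(cell$n_occurrences, 1)
  expect_equal(cell$n_species, 1)

  two <- summarize_by_phylum_region(rec(c("Lophelia pertusa", "Lophelia pertusa"),
                                        lat = c(-10, -12)))
  cell <- two[two$phylum == "Testa" & two$region == "tropical", ]
  expect_equal(cell$n_occurrences, 2)
  expect_equal(cell$n_species, 1)

  # regional split sits at 21 degrees S
  split <- summarize_by_phylum_region(rec(c("A b", "C d"), lat = c(-20.9, -21.0)))
  expect_equal(split[split$phylum == "Total" & split$region == "tropical",
                     "n_occurrences"], 1)
  expect_equal(split[split$phylum == "Total" & split$region == "subtropical",
                     "n_occurrences"], 1)
})

test_that("summary totals equal the curated record count", {
  fix <- two_group_fixture()
  cur <- curate(fix$records)
  tab <- summarize_by_phylum_region(cur$records)
  tot <- tab[tab$phylum == "Total", ]
  expect_equal(sum(tot$n_occurrences), nrow(cur$records))
})

test_that("the packaged phylum table replays through the summarizer cell-for-cell", {
  tab <- phylum_region_table()
  recs <- expand_phylum_region_table(tab)
  cur <- curate(recs)
  expect_equal(cur$report$n_retained, nrow(recs))  # pseudo-records survive curation
  got <- summarize_by_phylum_region(cur$records)
  for (i in which(tab$phylum != "Total")) {
    cell <- got[got$phylum == tab$phylum[i] & got$region == tab$region[i], ]
    if (tab$n_occurrences[i] == 0) {
      expect_true(nrow(cell) == 0 || cell$n_occurrences == 0)
    } else {
      expect_equal(cell$n_occurrences, tab$n_occurrences[i])
      expect_equal(cell$n_species, tab$n_species[i])
    }
  }
})
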