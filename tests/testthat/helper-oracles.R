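# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive results by the most literal route available
# (sets, from-scratch means) so they share no code path with the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# one occurrence record (or several, vectorized over arguments)
rec <- function(taxon = "Genusa species", lat = -10, lon = -38, depth = 500,
                phylum = "Testa", source = "test", rank = NA_character_) {
  data.frame(taxon_name = taxon, phylum = phylum, latitude = lat,
             longitude = lon, depth_m = depth, source_id = source,
             taxon_rank = rank, stringsAsFactors = FALSE)
}

# set-based Simpson turnover, computed literally from the definition
oracle_simpson <- function(x, y) {
  a <- length(intersect(x, y))
  b <- length(setdiff(x, y))
  cc <- length(setdiff(y, x))
  min(b, cc) / (min(b, cc) + a)
}

oracle_pairwise_simpson <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = dimnames(m)[c(1, 1)])
  sets <- apply(m, 1, function(r) colnames(m)[r == 1], simplify = FALSE)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) out[i, j] <- oracle_simpson(sets[[i]], sets[[j]])
  out
}

# from-scratch average linkage: cluster distances recomputed each step as
# the mean over all original cross-pairs (no Lance-Williams update), same
# tie rule (earliest pair in current order; values rounded to 12 decimals)
oracle_upgma_cophenetic <- function(D, label_order = rownames(D)) {
  clusters <- as.list(match(label_order, rownames(D)))
  C <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(1L, 2L)
    bestval <- Inf
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      v <- round(mean(D[clusters[[i]], clusters[[j]]]), 12)
      if (v < bestval) { bestval <- v; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    h <- mean(D[clusters[[i]], clusters[[j]]])
    for (p in clusters[[i]]) for (q in clusters[[j]]) C[p, q] <- C[q, p] <- h
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  C
}

# random symmetric dissimilarity in [0, 1]; coarse = round to 1 decimal to
# provoke exact ties
random_dissimilarity <- function(n, coarse = FALSE) {
  v <- stats::runif(n * (n - 1) / 2)
  if (coarse) v <- round(v, 1)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- v
  D <- D + t(D)
  dimnames(D) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  D
}

# random binary unit x species matrix with non-empty rows
random_pa <- function(n_units, n_species, p = 0.35) {
  m <- matrix(rbinom(n_units * n_species, 1, p), n_units, n_species,
              dimnames = list(paste0("U", seq_len(n_units)),
                              paste0("s", seq_len(n_species))))
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(n_species, sum(empty), replace = TRUE))] <- 1L
  m
}

all_label_orders <- function(labels) {
  n <- length(labels)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  perms(labels)
}

# planted two-group fixture used by several clustering tests
two_group_fixture <- function(u = 5, w = 5, g = 0, records = 60, seed = 1) {
  cfg <- synthetic_config(species_per_unit_unique = u,
                          species_shared_within_group = w,
                          species_shared_across_groups = g,
                          records_per_unit = records, seed = seed)
  truth <- generate_assemblages(cfg)
  recs <- generate_records(cfg, truth)
  pa <- drop_empty_units(build_presence_absence(recs, synthetic_assigner(truth)))
  list(cfg = cfg, truth = truth, records = recs, pa = pa)
}
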