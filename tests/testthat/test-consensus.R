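equidistant3 <- function() {
  D <- matrix(.5, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(D) <- 0
  D
}

test_that("three equidistant units give a star under exhaustive order enumeration", {
  D <- equidistant3()
  ct <- consensus_tree(D, resampling_config(seed = 1),
                       orders = all_label_orders(rownames(D)))
  expect_equal(length(ct$clusters), 1)          # only the root survives 50%
  expect_equal(ct$clusters[[1]]$members, c("A", "B", "C"))
  expect_equal(ct$clusters[[1]]$freq, 100)
  expect_match(as_newick(ct), "^\\(A:.*,B:.*,C:.*\\)100;$")
})

test_that("a tie-free matrix yields the unique UPGMA topology at frequency 100", {
  set.seed(91)
  D <- random_dissimilarity(5)
  ct <- consensus_tree(D, resampling_config(seed = 1, n_consensus_trees = 200))
  ref <- node_clusters(upgma(D))
  expect_setequal(vapply(ct$clusters, function(cl) paste(cl$members, collapse = "|"),
                         character(1)),
                  vapply(ref, paste, character(1), collapse = "|"))
  expect_true(all(vapply(ct$clusters, function(cl) cl$freq, numeric(1)) == 100))
})

test_that("planted groups are retained at full consensus frequency", {
  fix <- two_group_fixture(seed = 5)
  D <- pairwise_simpson(fix$pa)
  ct <- consensus_tree(D, resampling_config(seed = 1, n_consensus_trees = 200))
  keys <- vapply(ct$clusters, function(cl) paste(cl$members, collapse = "|"),
                 character(1))
  freqs <- vapply(ct$clusters, function(cl) cl$freq, numeric(1))
  for (grp in fix$cfg$planted_partition) {
    i <- match(paste(sort(grp), collapse = "|"), keys)
    expect_false(is.na(i))
    expect_equal(freqs[i], 100)
  }
})

test_that("retained frequencies audit against an independent recount of the same orders", {
  fix <- two_group_fixture(u = 2, w = 1, seed = 6)   # tie-rich matrix
  D <- pairwise_simpson(fix$pa)
  cfg <- resampling_config(seed = 9, n_consensus_trees = 120)
  ct <- consensus_tree(D, cfg)

  # regenerate the same substream and recount cluster frequencies per tree
  seeds <- deepbioreg:::derive_seeds(cfg$seed, "consensus", cfg$n_consensus_trees)
  counts <- list()
  for (s in seeds) {
    set.seed(s)
    ord <- rownames(D)[sample.int(nrow(D))]
    for (cl in node_clusters(upgma(D, ord))) {
      k <- paste(cl, collapse = "|")
      counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  for (cl in ct$clusters) {
    k <- paste(cl$members, collapse = "|")
    expect_gt(counts[[k]] / cfg$n_consensus_trees, cfg$consensus_threshold)
    expect_equal(100 * counts[[k]] / cfg$n_consensus_trees, cl$freq)
  }
})

test_that("consensus is deterministic under a fixed seed", {
  fix <- two_group_fixture(seed = 7)
  D <- pairwise_simpson(fix$pa)
  cfg <- resampling_config(seed = 33, n_consensus_trees = 80)
  expect_identical(consensus_tree(D, cfg), consensus_tree(D, cfg))
  cfg2 <- resampling_config(seed = 34, n_consensus_trees = 80)
  expect_s3_class(consensus_tree(D, cfg2), "consensus_tree")  # runs independently
})

test_that("fewer than three labels is an insufficient-data error", {
  D <- matrix(c(0, .3, .3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(consensus_tree(D, resampling_config(seed = 1)), "insufficient")
})

test_that("cutting the consensus recovers a planted partition exactly", {
  fix <- two_group_fixture(seed = 8)
  D <- pairwise_simpson(fix$pa)
  ct <- consensus_tree(D, resampling_config(seed = 2, n_consensus_trees = 150))
  part <- cut_consensus(ct, 2)
  expect_equal(rand_index(part, fix$truth$partition[names(part)]), 1.0)
})

test_that("dendrogram Newick strings carry ultrametric heights and round-trip", {
  D2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(as_newick(upgma(D2)), "(A:0.4,B:0.4);")

  set.seed(101)
  for (i in 1:10) {
    D <- random_dissimilarity(sample(4:7, 1))
    h <- upgma(D)
    p <- tempfile(fileext = ".nwk")
    write_newick(h, p)
    back <- ape::read.tree(p)
    expect_setequal(back$tip.label, rownames(D))
    # phylo cophenetic distances are leaf-to-leaf path lengths, i.e. twice
    # the ultrametric merge height
    got <- as.matrix(ape::cophenetic.phylo(back))[rownames(D), rownames(D)]
    want <- 2 * as.matrix(stats::cophenetic(h))[rownames(D), rownames(D)]
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("consensus Newick round-trips topology, labels and polytomies", {
  ct <- consensus_tree(equidistant3(), resampling_config(seed = 1),
                       orders = all_label_orders(c("A", "B", "C")))
  back <- ape::read.tree(text = as_newick(ct))
  expect_equal(back$Nnode, 1)                   # trifurcation at the root
  expect_setequal(back$tip.label, c("A", "B", "C"))

  fix <- two_group_fixture(seed = 9)
  D <- pairwise_simpson(fix$pa)
  ct2 <- consensus_tree(D, resampling_config(seed = 3, n_consensus_trees = 100))
  ph <- ape::as.phylo(ct2)
  expect_setequal(ph$tip.label, rownames(D))
  # every retained cluster is a clade of the re-parsed tree
  for (cl in ct2$clusters)
    expect_true(ape::is.monophyletic(ph, cl$members))
})
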