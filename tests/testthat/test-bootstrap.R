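small_cfg <- function(seed = 1, ...) {
  resampling_config(seed = seed, n_consensus_trees = 100, n_bootstrap = 60,
                    trees_per_bootstrap = 30, n_scales = 3, ...)
}

test_that("planted group nodes reach full bootstrap support; the root is always there", {
  fix <- two_group_fixture(seed = 1)
  D <- pairwise_simpson(fix$pa)
  cfg <- small_cfg()
  ct <- consensus_tree(D, cfg)
  bs <- bootstrap_support(fix$pa, ct, cfg)
  expect_equal(bs$support[bs$size == nrow(fix$pa)], 100)   # root
  for (grp in fix$cfg$planted_partition) {
    row <- bs[bs$members == paste(sort(grp), collapse = ";"), ]
    expect_equal(nrow(row), 1)
    expect_equal(row$support, 100)
  }
})

test_that("a single shared species collapses everything into an unsupported star", {
  # all units share the one species: every turnover is 0, replicate
  # consensuses are stars, so no resolved node can be recovered
  pa1 <- matrix(1L, 6, 1, dimnames = list(paste0("U", 1:6), "s1"))
  fix <- two_group_fixture(seed = 2)          # reference tree with resolved nodes
  cfg <- small_cfg()
  ct <- consensus_tree(pairwise_simpson(fix$pa), cfg)
  bs <- bootstrap_support(pa1, ct, cfg)
  resolved <- bs$size < nrow(pa1) & bs$size > 1
  expect_true(all(bs$support[resolved] <= 50))
  expect_equal(bs$support[bs$size == nrow(pa1)], 100)
})

test_that("bootstrap support is deterministic under a fixed seed", {
  fix <- two_group_fixture(u = 2, w = 2, seed = 3)
  cfg <- resampling_config(seed = 5, n_consensus_trees = 60, n_bootstrap = 25,
                           trees_per_bootstrap = 20, n_scales = 2)
  ct <- consensus_tree(pairwise_simpson(fix$pa), cfg)
  expect_identical(bootstrap_support(fix$pa, ct, cfg),
                   bootstrap_support(fix$pa, ct, cfg))
  expect_identical(multiscale_bootstrap(fix$pa, ct, cfg),
                   multiscale_bootstrap(fix$pa, ct, cfg))
})

test_that("a unit/leaf mismatch is an input error", {
  fix <- two_group_fixture(seed = 4)
  cfg <- small_cfg()
  ct <- consensus_tree(pairwise_simpson(fix$pa), cfg)
  expect_error(bootstrap_support(fix$pa[1:5, ], ct, cfg), "leaves differ")
})

test_that("a single-scale multiscale run reduces to the plain bootstrap", {
  fix <- two_group_fixture(u = 2, w = 2, seed = 5)
  cfg <- resampling_config(seed = 6, n_consensus_trees = 60, n_bootstrap = 30,
                           trees_per_bootstrap = 20, n_scales = 1)
  ct <- consensus_tree(pairwise_simpson(fix$pa), cfg)
  ms <- multiscale_bootstrap(fix$pa, ct, cfg)
  bs <- bootstrap_support(fix$pa, ct, cfg)
  expect_equal(unname(ms$support[, 1]), bs$support)
})

test_that("the root profile is flat at 100 across scales", {
  fix <- two_group_fixture(seed = 6)
  cfg <- small_cfg()
  ct <- consensus_tree(pairwise_simpson(fix$pa), cfg)
  ms <- multiscale_bootstrap(fix$pa, ct, cfg)
  root <- ms$nodes$size == nrow(fix$pa)
  expect_true(all(ms$support[root, ] == 100))
})

test_that("node labelling follows the slope-and-endpoint rule", {
  prof <- structure(list(
    nodes = data.frame(node = c("n1", "n2", "n3", "n4"),
                       size = c(6, 3, 3, 2), freq = 100,
                       members = c("a", "b", "c", "d"),
                       stringsAsFactors = FALSE),
    support = rbind(seq(60, 100, by = 10),
                    seq(80, 40, by = -10),
                    rep(50, 5),
                    c(70, 72, 71, 74, 80)),
    scales = 1:5), class = "node_support_profile")
  got <- identify_nodes(prof)
  expect_equal(got$nodes$label,
               c("supported", "unsupported", "unsupported", "supported"))
  expect_equal(got$nodes$slope[1], 10)
  expect_error(identify_nodes(structure(list(nodes = prof$nodes,
                                             support = prof$support[, 1, drop = FALSE],
                                             scales = 1),
                                        class = "node_support_profile")),
               "2 scales")
})

test_that("more cross-group sharing never raises mean group-node support", {
  # pools large enough that species drop-out is negligible; degradation
  # then comes only from the shrinking within/between turnover contrast
  mean_group_support <- function(g, seed) {
    fix <- two_group_fixture(u = 5, w = 10, g = g, records = 60 + 6 * g,
                             seed = seed)
    cfg <- resampling_config(seed = seed, n_consensus_trees = 60,
                             n_bootstrap = 40, trees_per_bootstrap = 20,
                             n_scales = 1)
    ct <- consensus_tree(pairwise_simpson(fix$pa), cfg)
    keys <- vapply(fix$cfg$planted_partition,
                   function(grp) paste(sort(grp), collapse = ";"), character(1))
    bs <- bootstrap_support(fix$pa, ct, cfg)
    mean(bs$support[match(keys, bs$members)], na.rm = TRUE)
  }
  gs <- c(0, 20, 90)
  sup <- sapply(gs, function(g) mean(sapply(1:2, function(s)
    mean_group_support(g, s))))
  expect_true(all(diff(sup) <= 1e-9))
})

test_that("support tables serialize with per-scale columns and labels", {
  fix <- two_group_fixture(seed = 7)
  cfg <- resampling_config(seed = 2, n_consensus_trees = 50, n_bootstrap = 20,
                           trees_per_bootstrap = 15, n_scales = 2)
  ct <- consensus_tree(pairwise_simpson(fix$pa), cfg)
  pr <- identify_nodes(multiscale_bootstrap(fix$pa, ct, cfg))
  p <- tempfile(fileext = ".csv")
  write_support_table(pr, p)
  back <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_equal(nrow(back), length(ct$clusters))
  expect_true(all(c("X1", "X2", "label", "slope") %in% names(back)))
})
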