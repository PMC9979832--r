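# Majority-rule consensus over order-randomized UPGMA dendrograms.
#
# A single UPGMA run on a tie-laden turnover matrix commits silently to one
# of many equivalent topologies. Re-running UPGMA under many random label
# orders and keeping only the clusters that appear in a strict majority of
# runs yields a (possibly multifurcating) consensus whose resolved nodes are
# order-robust; everything order-dependent collapses into polytomies.

#' Resampling parameters
#'
#' One bundle for every randomized stage: the order-randomized consensus,
#' the species bootstrap and the multiscale bootstrap. All randomness is
#' driven by `seed` through counter-indexed substreams, so identical
#' configurations reproduce results bit for bit regardless of execution
#' order.
#'
#' @param seed master integer seed (mandatory: runs must be replayable).
#' @param n_consensus_trees random label orders per consensus (default
#'   1,000).
#' @param consensus_threshold retention rule: a cluster is kept when its
#'   frequency strictly exceeds this proportion (default 0.5, strict
#'   majority; must be in \[0.5, 1) so retained clusters are mutually
#'   compatible).
#' @param n_bootstrap species-resampling replicates (default 1,000).
#' @param trees_per_bootstrap random label orders per replicate consensus
#'   (default 100).
#' @param n_scales multiscale bootstrap levels (default 10): level k
#'   resamples k times the observed species count.
#' @return object of class `resampling_config`.
#' @export
resampling_config <- function(seed,
                              n_consensus_trees = 1000,
                              consensus_threshold = 0.5,
                              n_bootstrap = 1000,
                              trees_per_bootstrap = 100,
                              n_scales = 10) {
  if (missing(seed)) stop_input("seed is mandatory (runs must be replayable)")
  assert_numeric_scalar(seed, "seed")
  for (nm in c("n_consensus_trees", "n_bootstrap", "trees_per_bootstrap",
               "n_scales"))
    assert_numeric_scalar(get(nm), nm, lower = 1)
  assert_numeric_scalar(consensus_threshold, "consensus_threshold")
  if (consensus_threshold < 0.5 || consensus_threshold >= 1)
    stop_input("consensus_threshold must lie in [0.5, 1)")
  structure(list(seed = as.integer(seed),
                 n_consensus_trees = as.integer(n_consensus_trees),
                 consensus_threshold = consensus_threshold,
                 n_bootstrap = as.integer(n_bootstrap),
                 trees_per_bootstrap = as.integer(trees_per_bootstrap),
                 n_scales = as.integer(n_scales)),
            class = "resampling_config")
}

# count cluster occurrences (and accumulate heights) over UPGMA runs under
# the given integer permutations of D's labels
consensus_counts <- function(D, perms) {
  counts <- new.env(parent = emptyenv())
  heights <- new.env(parent = emptyenv())
  members <- new.env(parent = emptyenv())
  for (perm in perms) {
    h <- upgma_core(D, perm)
    cl <- node_clusters(h)
    for (s in seq_along(cl)) {
      key <- cluster_key(cl[[s]])
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      heights[[key]] <- (heights[[key]] %||% 0) + h$height[s]
      if (is.null(members[[key]])) members[[key]] <- cl[[s]]
    }
  }
  list(counts = counts, heights = heights, members = members)
}

random_perms <- function(n_labels, n_perms, seed, stream) {
  seeds <- derive_seeds(seed, stream, n_perms)
  lapply(seq_len(n_perms), function(i) {
    set.seed(seeds[i])
    sample.int(n_labels)
  })
}

#' Majority-rule consensus of order-randomized UPGMA trees
#'
#' Runs [upgma()] under many random label orders of the same dissimilarity
#' matrix and assembles the clusters appearing in a strict majority of runs
#' into a consensus tree. Tie-free matrices give a fully resolved consensus
#' with every node at 100; fully tied regions of the matrix collapse into
#' polytomies.
#'
#' @param D symmetric dissimilarity matrix (at least 3 units).
#' @param cfg a [resampling_config()]; `n_consensus_trees`,
#'   `consensus_threshold` and `seed` are used.
#' @param orders optional explicit list of label orders (character vectors),
#'   overriding random sampling — e.g. all `factorial(n)` permutations for
#'   exhaustive enumeration on small problems.
#' @return object of class `consensus_tree`: `labels`, and `clusters`, a
#'   list (decreasing size; root first) of `members` (sorted leaf labels),
#'   `freq` (percent of runs containing the cluster) and `height` (mean
#'   merge height over the runs containing it).
#' @export
consensus_tree <- function(D, cfg, orders = NULL) {
  D <- validate_dissimilarity(D)
  n <- nrow(D)
  if (n < 3) stop_input("insufficient data: consensus needs at least 3 units")
  stopifnot(inherits(cfg, "resampling_config"))
  labels <- rownames(D)
  if (is.null(orders)) {
    perms <- random_perms(n, cfg$n_consensus_trees, cfg$seed, "consensus")
  } else {
    perms <- lapply(orders, function(o) {
      p <- match(o, labels)
      if (anyNA(p) || length(p) != n) stop_input("orders must permute the unit labels")
      p
    })
  }
  acc <- consensus_counts(D, perms)
  n_trees <- length(perms)
  keys <- ls(acc$counts)
  freq <- vapply(keys, function(k) 100 * acc$counts[[k]] / n_trees, numeric(1))
  keep <- freq > 100 * cfg$consensus_threshold
  keys <- keys[keep]; freq <- freq[keep]
  clusters <- lapply(seq_along(keys), function(i) {
    k <- keys[i]
    list(members = acc$members[[k]], freq = unname(freq[i]),
         height = acc$heights[[k]] / acc$counts[[k]])
  })
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  clusters <- clusters[order(-sizes, keys)]
  structure(list(labels = sort(labels), clusters = clusters,
                 n_trees = n_trees, threshold = cfg$consensus_threshold),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("Consensus of %d order-randomized UPGMA trees (> %.0f%% rule)\n",
              x$n_trees, 100 * x$threshold))
  cat(sprintf("%d leaves, %d retained clusters:\n",
              length(x$labels), length(x$clusters)))
  for (cl in x$clusters)
    cat(sprintf("  [%5.1f%%] {%s}\n", cl$freq, paste(cl$members, collapse = ", ")))
  invisible(x)
}

# indices of each retained cluster's direct parent (smallest strictly
# containing retained cluster); NA for the root
consensus_parents <- function(tree) {
  k <- length(tree$clusters)
  sizes <- vapply(tree$clusters, function(cl) length(cl$members), integer(1))
  vapply(seq_len(k), function(i) {
    sup <- which(vapply(seq_len(k), function(j) {
      sizes[j] > sizes[i] && all(tree$clusters[[i]]$members %in%
                                   tree$clusters[[j]]$members)
    }, logical(1)))
    if (!length(sup)) NA_integer_ else sup[which.min(sizes[sup])]
  }, integer(1))
}

#' Cut a consensus tree into k groups
#'
#' Starting from the root's direct children, repeatedly splits the
#' highest-merging resolved cluster into its own children until at least
#' `k` parts exist (or nothing is left to split). Leaves not covered by a
#' retained child cluster become singleton parts.
#'
#' @param tree a [consensus_tree()].
#' @param k target number of groups.
#' @return named integer vector: group id per leaf label.
#' @export
cut_consensus <- function(tree, k) {
  stopifnot(inherits(tree, "consensus_tree"))
  parents <- consensus_parents(tree)
  children_of <- function(i) which(parents == i)
  part_of <- function(i) {     # a part: cluster index (>0) or leaf label
    kids <- children_of(i)
    covered <- unlist(lapply(kids, function(j) tree$clusters[[j]]$members))
    loose <- setdiff(tree$clusters[[i]]$members, covered)
    c(as.list(kids), as.list(loose))
  }
  root <- which(is.na(parents))
  parts <- part_of(root)
  repeat {
    if (length(parts) >= k) break
    splittable <- which(vapply(parts, function(p)
      is.numeric(p) && length(children_of(p)) > 0, logical(1)))
    if (!length(splittable)) break
    hts <- vapply(splittable, function(s) tree$clusters[[parts[[s]]]]$height,
                  numeric(1))
    s <- splittable[which.max(hts)]
    parts <- c(parts[-s], part_of(parts[[s]]))
  }
  out <- integer(0)
  for (g in seq_along(parts)) {
    p <- parts[[g]]
    mem <- if (is.numeric(p)) tree$clusters[[p]]$members else p
    out[mem] <- g
  }
  out[tree$labels]
}
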