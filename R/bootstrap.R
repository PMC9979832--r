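# Species-resampling bootstrap support for consensus nodes, the multiscale
# extension, and trend-based node classification.
#
# Units are the objects being classified, so rows are never resampled:
# each replicate draws species columns with replacement, recomputes the
# Simpson matrix, builds its own order-randomized consensus, and scores a
# node as recovered when the replicate consensus contains the node's exact
# leaf cluster. A unit that loses every species in a replicate drops out of
# that replicate, so nodes containing it cannot be recovered there.

tree_node_table <- function(tree) {
  stopifnot(inherits(tree, "consensus_tree"))
  keys <- vapply(tree$clusters, function(cl) cluster_key(cl$members), character(1))
  data.frame(node = paste0("n", seq_along(tree$clusters)),
             size = vapply(tree$clusters, function(cl) length(cl$members), integer(1)),
             freq = vapply(tree$clusters, function(cl) cl$freq, numeric(1)),
             members = vapply(tree$clusters, function(cl)
               paste(cl$members, collapse = ";"), character(1)),
             key = keys, stringsAsFactors = FALSE)
}

# one bootstrap replicate: which of `keys` appear in the replicate consensus?
bootstrap_replicate <- function(pa, keys, cols, trees_per_bootstrap,
                                threshold, order_seeds) {
  sub <- pa[, cols, drop = FALSE]
  keep <- rowSums(sub) > 0
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < 2) return(rep(FALSE, length(keys)))
  D <- pairwise_simpson(sub)
  perms <- lapply(order_seeds, function(s) { set.seed(s); sample.int(nrow(D)) })
  acc <- consensus_counts(D, perms)
  hit_keys <- ls(acc$counts)
  n_trees <- length(perms)
  retained <- hit_keys[vapply(hit_keys, function(k)
    acc$counts[[k]] / n_trees > threshold, logical(1))]
  keys %in% retained
}

#' Bootstrap node support for a consensus tree
#'
#' For each of `cfg$n_bootstrap` replicates: species columns are resampled
#' with replacement (same column count), the Simpson matrix is recomputed,
#' a consensus of `cfg$trees_per_bootstrap` order-randomized UPGMA trees is
#' built, and every node of `tree` scores 1 when the replicate consensus
#' contains its exact leaf cluster. Support is the percentage of replicates
#' recovering the node.
#'
#' @param pa binary presence/absence matrix; its row names must equal the
#'   tree's leaf labels.
#' @param tree the reference [consensus_tree()] whose nodes are scored.
#' @param cfg a [resampling_config()].
#' @param n_columns number of columns drawn per replicate; defaults to
#'   `ncol(pa)` (the plain bootstrap). The multiscale wrapper passes
#'   multiples of it.
#' @param stream internal substream tag (distinct per scale).
#' @return data frame with one row per node: `node`, `size`, `freq`
#'   (consensus frequency), `members`, `support` (percent of replicates).
#' @export
bootstrap_support <- function(pa, tree, cfg, n_columns = ncol(pa),
                              stream = "bootstrap.x1") {
  stopifnot(is.matrix(pa), inherits(cfg, "resampling_config"))
  if (!setequal(rownames(pa), tree$labels))
    stop_input("input error: matrix units and tree leaves differ")
  nodes <- tree_node_table(tree)
  col_seeds <- derive_seeds(cfg$seed, paste0(stream, ".columns"), cfg$n_bootstrap)
  ord_seeds <- matrix(
    derive_seeds(cfg$seed, paste0(stream, ".orders"),
                 cfg$n_bootstrap * cfg$trees_per_bootstrap),
    nrow = cfg$n_bootstrap)
  hits <- matrix(FALSE, cfg$n_bootstrap, nrow(nodes))
  for (r in seq_len(cfg$n_bootstrap)) {
    set.seed(col_seeds[r])
    cols <- sample.int(ncol(pa), n_columns, replace = TRUE)
    hits[r, ] <- bootstrap_replicate(pa, nodes$key, cols,
                                     cfg$trees_per_bootstrap,
                                     cfg$consensus_threshold, ord_seeds[r, ])
  }
  nodes$support <- 100 * colMeans(hits)
  nodes$key <- NULL
  nodes
}

#' Multiscale bootstrap support profiles
#'
#' Repeats [bootstrap_support()] at resample sizes that are multiples of
#' the observed species count: scale k draws `k * ncol(pa)` columns with
#' replacement. Larger scales give every species a better chance of
#' entering the replicate, so genuine nodes gain support with scale while
#' artefacts of sparse sampling do not.
#'
#' @inheritParams bootstrap_support
#' @return object of class `node_support_profile`: the node table plus a
#'   `support` matrix (nodes x scales, percent) and the scale vector.
#' @export
multiscale_bootstrap <- function(pa, tree, cfg) {
  stopifnot(inherits(cfg, "resampling_config"))
  nodes <- tree_node_table(tree)
  sup <- matrix(NA_real_, nrow(nodes), cfg$n_scales,
                dimnames = list(nodes$node, paste0("X", seq_len(cfg$n_scales))))
  for (k in seq_len(cfg$n_scales)) {
    # scale 1 shares the plain bootstrap's substream, so a 1-scale
    # multiscale run reproduces bootstrap_support() exactly
    bk <- bootstrap_support(pa, tree, cfg, n_columns = k * ncol(pa),
                            stream = sprintf("bootstrap.x%d", k))
    sup[, k] <- bk$support
  }
  nodes$key <- NULL
  structure(list(nodes = nodes, support = sup,
                 scales = seq_len(cfg$n_scales)),
            class = "node_support_profile")
}

#' @export
print.node_support_profile <- function(x, ...) {
  cat(sprintf("Node support at %d bootstrap scales:\n", length(x$scales)))
  df <- cbind(x$nodes[c("node", "size", "freq")], round(x$support, 1))
  if (!is.null(x$nodes$label)) df$label <- x$nodes$label
  print(df, row.names = FALSE)
  invisible(x)
}

#' Classify nodes by their support trend across scales
#'
#' A node is labelled `"supported"` when its support grows with the
#' bootstrap scale — operationalized as a strictly positive least-squares
#' slope of support against scale *and* higher support at the top scale
#' than at scale 1 — and `"unsupported"` otherwise (flat or decreasing
#' trends indicate sampling artefacts rather than signal).
#'
#' @param profile a [multiscale_bootstrap()] result (at least 2 scales).
#' @return the profile with a `label` column added to its node table and a
#'   `slope` column (support percent per scale step).
#' @export
identify_nodes <- function(profile) {
  stopifnot(inherits(profile, "node_support_profile"))
  if (length(profile$scales) < 2)
    stop_input("input error: need at least 2 scales to assess a trend")
  x <- profile$scales
  xc <- x - mean(x)
  slope <- as.numeric(profile$support %*% xc) / sum(xc^2)
  last <- profile$support[, length(x)]
  first <- profile$support[, 1]
  profile$nodes$slope <- slope
  profile$nodes$label <- ifelse(slope > 0 & last > first,
                                "supported", "unsupported")
  profile
}

#' Write a node support table as CSV
#'
#' One row per node: id, leaf set, consensus frequency, support per scale
#' and (when [identify_nodes()] has run) slope and label.
#'
#' @param profile a `node_support_profile`.
#' @param path output file.
#' @export
write_support_table <- function(profile, path) {
  df <- cbind(profile$nodes, profile$support)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
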