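# Order-sensitive UPGMA (average linkage) agglomeration.
#
# Turnover matrices carry many exactly tied distances (nested assemblages
# all at 0), and under ties the agglomeration order decides the topology.
# Rather than hiding that behind an arbitrary internal scan order, the
# tie-break is explicit: among all pairs attaining the minimal distance,
# the pair earliest in the *current label order* is merged (smallest first
# position, then smallest second). Feeding random label orders to this one
# deterministic rule is what the consensus machinery builds on.
#
# Distances are compared after rounding to 12 significant decimals so that
# mathematically tied values stay tied under floating-point re-association.

TIE_DIGITS <- 12

#' UPGMA dendrogram under an explicit label order
#'
#' Average-linkage agglomerative clustering of a dissimilarity matrix with
#' a deterministic order-based tie-break (see Details). Returns a
#' [stats::hclust]-compatible object, so [stats::cophenetic()],
#' [stats::cutree()], plotting and [ape::as.phylo()] all apply.
#'
#' @details At every step the two clusters at minimal average dissimilarity
#'   are merged at a height equal to that dissimilarity (the mean of all
#'   between-cluster pair dissimilarities of the input matrix). When several
#'   pairs tie for the minimum, the pair that comes first in `label_order`
#'   (by its earlier member, then by its later member) is merged; the merged
#'   cluster keeps the position of its earlier member. A tie-free matrix
#'   therefore yields the same topology under every label order, while tied
#'   matrices expose their ambiguity through order dependence.
#'
#' @param D symmetric dissimilarity matrix with entries in \[0, 1\] and zero
#'   diagonal (see [pairwise_simpson()]).
#' @param label_order permutation of `rownames(D)` used for tie-breaking;
#'   defaults to the matrix order.
#' @return an object of class `hclust` (components `merge`, `height`,
#'   `order`, `labels`, `method = "upgma"`).
#' @export
upgma <- function(D, label_order = rownames(D)) {
  D <- validate_dissimilarity(D)
  labels <- rownames(D)
  n <- length(labels)
  if (n < 2) stop_input("input error: need at least 2 units")
  if (length(label_order) != n || !setequal(label_order, labels) ||
      anyDuplicated(label_order))
    stop_input("input error: label_order must be a permutation of the matrix labels")
  upgma_core(D, match(label_order, labels))
}

# core agglomeration; D validated, perm an integer permutation
upgma_core <- function(D, perm) {
  labels <- rownames(D)
  n <- length(labels)
  M <- D[perm, perm, drop = FALSE]
  ids <- -perm                      # hclust node ids (negative = leaf)
  sizes <- rep(1, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(ids)
    R <- round(M, TIE_DIGITS)
    best_i <- 1L; best_j <- 2L; best <- R[1L, 2L]
    if (k > 2L) {
      for (i in seq_len(k - 1L)) {
        row <- R[i, (i + 1L):k]
        j_rel <- which.min(row)     # first minimum: smallest j
        if (row[j_rel] < best) {    # strict: earliest i wins ties
          best <- row[j_rel]; best_i <- i; best_j <- i + j_rel
        }
      }
    }
    merge[step, ] <- c(ids[best_i], ids[best_j])
    height[step] <- M[best_i, best_j]
    new_row <- (sizes[best_i] * M[best_i, ] + sizes[best_j] * M[best_j, ]) /
      (sizes[best_i] + sizes[best_j])
    M[best_i, ] <- new_row
    M[, best_i] <- new_row
    M[best_i, best_i] <- 0
    sizes[best_i] <- sizes[best_i] + sizes[best_j]
    ids[best_i] <- step
    M <- M[-best_j, -best_j, drop = FALSE]
    ids <- ids[-best_j]; sizes <- sizes[-best_j]
  }
  structure(list(merge = merge, height = height,
                 order = hclust_leaf_order(merge, n),
                 labels = labels, method = "upgma",
                 dist.method = "simpson"),
            class = "hclust")
}

hclust_leaf_order <- function(merge, n) {
  rec <- function(id) {
    if (id < 0) return(-id)
    c(rec(merge[id, 1L]), rec(merge[id, 2L]))
  }
  rec(n - 1L)
}

#' Leaf clusters of a dendrogram's internal nodes
#'
#' @param h an `hclust` object (e.g. from [upgma()]).
#' @return list with one sorted character vector of leaf labels per merge
#'   step (the last element is the full leaf set, i.e. the root).
#' @export
node_clusters <- function(h) {
  stopifnot(inherits(h, "hclust"))
  n <- length(h$labels)
  members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get1 <- function(id) if (id < 0) h$labels[-id] else members[[id]]
    members[[s]] <- sort(c(get1(h$merge[s, 1L]), get1(h$merge[s, 2L])))
  }
  members
}

cluster_key <- function(members) paste(members, collapse = "\r")
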