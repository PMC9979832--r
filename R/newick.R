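# Newick export for dendrograms and consensus trees.

newick_safe <- function(x) gsub("[ ,:;()\\[\\]']", "_", x)

#' Newick string for a tree
#'
#' For an `hclust` dendrogram the string encodes the ultrametric heights
#' (each branch length is the difference between parent and child merge
#' heights; leaves sit at height 0). For a `consensus_tree` the internal
#' node labels carry the consensus frequency (percent) and branch lengths
#' derive from mean merge heights (clamped at 0, since means over different
#' run subsets can invert slightly).
#'
#' @param tree an `hclust` (see [upgma()]) or [consensus_tree()] object.
#' @return a single Newick string, semicolon-terminated.
#' @export
as_newick <- function(tree) UseMethod("as_newick")

#' @export
as_newick.hclust <- function(tree) {
  n <- length(tree$labels)
  lab <- newick_safe(tree$labels)
  rec <- function(id, parent_h) {
    if (id < 0)
      return(sprintf("%s:%s", lab[-id], format(parent_h, digits = 10)))
    h <- tree$height[id]
    sprintf("(%s,%s):%s", rec(tree$merge[id, 1], h), rec(tree$merge[id, 2], h),
            format(parent_h - h, digits = 10))
  }
  root_h <- tree$height[n - 1]
  inner <- paste(rec(tree$merge[n - 1, 1], root_h),
                 rec(tree$merge[n - 1, 2], root_h), sep = ",")
  paste0("(", inner, ");")
}

#' @export
as_newick.consensus_tree <- function(tree) {
  parents <- consensus_parents(tree)
  children_of <- function(i) which(parents == i)
  lab <- structure(newick_safe(tree$labels), names = tree$labels)
  rec <- function(i, parent_h) {
    cl <- tree$clusters[[i]]
    kids <- children_of(i)
    covered <- unlist(lapply(kids, function(j) tree$clusters[[j]]$members))
    loose <- setdiff(cl$members, covered)
    parts <- c(
      vapply(kids, function(j) rec(j, cl$height), character(1)),
      vapply(loose, function(l) sprintf("%s:%s", lab[[l]],
                                        format(cl$height, digits = 10)),
             character(1)))
    blen <- max(parent_h - cl$height, 0)
    sprintf("(%s)%s:%s", paste(parts, collapse = ","),
            format(cl$freq, digits = 4), format(blen, digits = 10))
  }
  root <- which(is.na(parents))
  s <- rec(root, tree$clusters[[root]]$height)
  # strip the root's zero-length branch
  paste0(sub(":[^:]*$", "", s), ";")
}

#' Write a tree to a Newick file
#'
#' The written file round-trips through [ape::read.tree()] with identical
#' topology and leaf labels.
#'
#' @param tree an `hclust` or `consensus_tree` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(as_newick(tree), path)
  invisible(path)
}

#' Convert a consensus tree to an ape phylogeny
#'
#' @param x a [consensus_tree()].
#' @param ... unused.
#' @return an `ape` `phylo` object (consensus frequencies as node labels).
#' @exportS3Method ape::as.phylo
as.phylo.consensus_tree <- function(x, ...) {
  ape::read.tree(text = as_newick(x))
}
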