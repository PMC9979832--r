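# Simpson turnover dissimilarity between unit assemblages.
#
# With a = species shared by two units and b, c = species exclusive to each,
# the turnover component of beta diversity is
#     beta_sim = min(b, c) / (min(b, c) + a).
# Unlike Sorensen dissimilarity it ignores the richness difference |b - c|:
# a poor assemblage nested in a rich one scores 0, so depauperate units are
# not pushed apart merely for having been sampled less.

#' Simpson turnover dissimilarity between two species sets
#'
#' @param x,y character vectors of species names (non-empty; duplicates
#'   ignored). Empty assemblages are an error rather than 0 or NA — empty
#'   units must be removed upstream with [drop_empty_units()], so meeting
#'   one here is a pipeline bug.
#' @return a number in \[0, 1\]: 0 iff one set is nested in (or equal to)
#'   the other, 1 iff the sets are disjoint.
#' @export
simpson_dissimilarity <- function(x, y) {
  x <- unique(as.character(x)); y <- unique(as.character(y))
  if (length(x) == 0 || length(y) == 0)
    stop_input("undefined input: empty assemblage (remove empty units upstream)")
  a <- length(intersect(x, y))
  m <- min(length(x), length(y)) - a   # min(b, c)
  m / (m + a)
}

#' Pairwise Simpson turnover matrix
#'
#' Computes the full symmetric unit-by-unit Simpson dissimilarity matrix
#' from a binary presence/absence matrix.
#'
#' @param m binary matrix, units in rows, species in columns; at least two
#'   units, none empty.
#' @return symmetric numeric matrix with zero diagonal and unit labels as
#'   dimnames.
#' @export
pairwise_simpson <- function(m) {
  stopifnot(is.matrix(m))
  if (!all(m %in% c(0L, 1L))) stop_input("matrix must be binary 0/1")
  if (nrow(m) < 2)
    stop_input("insufficient data: need at least 2 non-empty units")
  rich <- rowSums(m)
  if (any(rich == 0))
    stop_input("undefined input: empty unit row (remove empty units upstream)")
  storage.mode(m) <- "double"
  a <- m %*% t(m)                         # shared species counts
  minbc <- outer(rich, rich, pmin) - a    # min(b, c)
  D <- minbc / (minbc + a)
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

validate_dissimilarity <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop_input("input error: dissimilarity must be a square matrix")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("U", seq_len(nrow(D)))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-9, check.attributes = FALSE)))
    stop_input("input error: dissimilarity matrix is not symmetric")
  if (any(D < -1e-12) || any(D > 1 + 1e-12))
    stop_input("input error: dissimilarity entries must lie in [0, 1]")
  if (any(abs(diag(D)) > 1e-12))
    stop_input("input error: dissimilarity diagonal must be zero")
  D
}

#' Diagnose tied dissimilarity values
#'
#' Turnover matrices from incidence data are tie-prone — nested assemblages
#' all sit at exactly 0 — and ties are what make single-order UPGMA
#' topologies arbitrary. This report quantifies the problem over the strict
#' upper triangle.
#'
#' @param D symmetric dissimilarity matrix.
#' @return object of class `tie_report`: `n_pairs`, `n_zero_pairs`,
#'   `n_tied_groups` (distinct values shared by more than one pair) and
#'   `max_tie_multiplicity` (largest number of pairs sharing one value; 1
#'   when all values are distinct).
#' @export
tie_report <- function(D) {
  D <- validate_dissimilarity(D)
  vals <- D[upper.tri(D)]
  key <- signif(vals, 12)
  tab <- table(key)
  structure(list(n_pairs = length(vals),
                 n_zero_pairs = sum(vals < 1e-12),
                 n_tied_groups = sum(tab > 1),
                 max_tie_multiplicity = if (length(tab)) max(tab) else 0L),
            class = "tie_report")
}

#' @export
print.tie_report <- function(x, ...) {
  cat(sprintf("Ties: %d pairs, %d at zero, %d tied value groups (max multiplicity %d)\n",
              x$n_pairs, x$n_zero_pairs, x$n_tied_groups, x$max_tie_multiplicity))
  invisible(x)
}

#' Write / read a dissimilarity matrix as CSV
#'
#' Square layout with unit labels both as header and as first column.
#'
#' @param D symmetric matrix.
#' @param path file path.
#' @return `read_dissimilarity` returns the labelled numeric matrix.
#' @export
write_dissimilarity <- function(D, path) {
  df <- data.frame(unit_id = rownames(D), D, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissimilarity
#' @export
read_dissimilarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_dissimilarity(m)
}
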