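# Internal helpers: validation and reproducible substreams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_numeric_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_input(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper))
  x
}

# Deterministic per-stream seeds derived from one master seed. Each named
# stream gets its own block of counter-indexed sub-seeds, so replicate i
# always sees the same RNG state regardless of how many other streams ran
# before it (execution-order independence).
derive_seeds <- function(master_seed, stream, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, !is.na(master_seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 1000003L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(master_seed) %% 1000000000L) + h)
  sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
}

# Pair-counting Rand index between two partitions of the same objects.
# 1 means identical groupings. Used to score planted-partition recovery.
#' Rand index between two partitions
#'
#' Agreement between two labellings of the same objects, computed by pair
#' counting: the proportion of object pairs on which the two partitions agree
#' (both together or both apart). Equals 1 for identical partitions.
#'
#' @param a,b vectors of group labels of equal length (names ignored).
#' @return a number in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("partitions must cover the same objects")
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
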