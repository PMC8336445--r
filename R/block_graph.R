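# Largest integer e with e < t * L (edit-distance bound equivalent to
# divergence strictly below t at maximum length L).
strict_edit_bound <- function(t, L) as.integer(ceiling(t * L - 1e-9)) - 1L

#' Build the block-graph of unresolved blocks
#'
#' Vertices are blocks; an edge connects two blocks whose divergence is
#' strictly below `threshold` (by default half the resolved-divergence
#' threshold). For large inputs, candidate pairs are prefiltered by shared
#' q-gram counts (q-gram lemma, so no qualifying pair is missed) and a
#' length-difference bound, then verified with a banded edit distance.
#'
#' @param blocks A block tibble with a `seq` column, or a character vector of
#'   block sequences.
#' @param threshold Divergence threshold (edges strictly below it).
#' @param brute_force_below Use all-pairs verification when there are at most
#'   this many blocks (also used when blocks are shorter than the q-gram).
#' @return A `block_graph`: list with `n`, `edges` (tibble `from`, `to`,
#'   `divergence`), `membership` (component id per block) and `sizes`.
#' @export
build_block_graph <- function(blocks, threshold, brute_force_below = 400L) {
  seqs <- if (is.data.frame(blocks)) blocks$seq else blocks
  stopifnot(is.character(seqs), threshold > 0)
  n <- length(seqs)
  if (n <= 1L) {
    memb <- rep(1L, n)
    return(structure(list(n = n,
                          edges = tibble(from = integer(0), to = integer(0),
                                         divergence = numeric(0)),
                          membership = memb, sizes = rep(1L, n)),
                     class = "block_graph"))
  }
  len <- nchar(seqs)
  q <- 7L
  if (n <= brute_force_below || min(len) <= q) {
    pairs <- utils::combn(n, 2L)
    cand_i <- pairs[1L, ]; cand_j <- pairs[2L, ]
  } else {
    cand <- qgram_candidate_pairs(seqs, len, threshold, q)
    cand_i <- cand$i; cand_j <- cand$j
  }
  if (length(cand_i) == 0L) {
    edges <- tibble(from = integer(0), to = integer(0), divergence = numeric(0))
  } else {
    maxlen <- pmax(len[cand_i], len[cand_j])
    kmax <- strict_edit_bound(threshold, maxlen)
    d <- cpp_bounded_edit_pairs(seqs, cand_i, cand_j, kmax)
    keep <- d >= 0L
    edges <- tibble(from = cand_i[keep], to = cand_j[keep],
                    divergence = d[keep] / maxlen[keep])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  memb <- comp$membership[as.character(seq_len(n))]
  structure(list(n = n, edges = edges, membership = as.integer(memb),
                 sizes = as.integer(comp$csize)),
            class = "block_graph")
}

# Shared q-gram prefilter: strings within edit distance e share at least
# (min_len - q + 1) - e*q q-gram occurrences (q-gram lemma), and differ in
# length by at most e. The count-profile inner product upper-bounds the
# occurrence-match count, so no qualifying pair is dropped.
qgram_candidate_pairs <- function(seqs, len, threshold, q = 7L) {
  n <- length(seqs)
  grams <- lapply(seqs, function(s) {
    substring(s, 1:(nchar(s) - q + 1L), q:nchar(s))
  })
  all_g <- unique(unlist(grams, use.names = FALSE))
  idx <- lapply(grams, function(g) match(g, all_g))
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), lengths(idx)),
    j = unlist(idx, use.names = FALSE),
    x = 1, dims = c(n, length(all_g)))  # duplicate (i,j) entries are summed
  shared <- Matrix::tcrossprod(A)
  tr <- Matrix::summary(shared)
  keep <- tr$i < tr$j
  i <- tr$i[keep]; j <- tr$j[keep]; sh <- tr$x[keep]
  maxlen <- pmax(len[i], len[j]); minlen <- pmin(len[i], len[j])
  emax <- strict_edit_bound(threshold, maxlen)
  ok <- (maxlen - minlen) <= emax & sh >= (minlen - q + 1L) - emax * q
  list(i = i[ok], j = j[ok])
}

#' @export
print.block_graph <- function(x, ...) {
  cat("<block_graph> ", x$n, " blocks, ", nrow(x$edges), " edges, ",
      length(x$sizes), " components (largest ",
      if (length(x$sizes)) max(x$sizes) else 0L, ")\n", sep = "")
  invisible(x)
}
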