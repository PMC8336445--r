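#' Edit distance between nucleotide strings
#'
#' Unit-cost Levenshtein distance (match 0, mismatch/insertion/deletion 1).
#' Vectorized elementwise with recycling.
#'
#' @param a,b Character vectors of nucleotide strings (empty strings allowed).
#' @return Integer vector of edit distances.
#' @examples
#' edit_distance("ACGT", "ACGT")
#' edit_distance("AGGT", "AGT")
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(adist(a[i], b[i])[1L, 1L]),
         integer(1))
}

#' Divergence between nucleotide strings
#'
#' Edit distance divided by the length of the longer string, a fraction in
#' \[0, 1\]. Symmetric; 0 exactly when the strings are equal.
#'
#' @inheritParams edit_distance
#' @return Numeric vector of divergences.
#' @examples
#' divergence("ACGT", "ACGA")  # 0.25
#' @export
divergence <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  n <- max(length(a), length(b))
  if (n == 0L) return(numeric(0))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  len <- pmax(nchar(a), nchar(b))
  if (any(len == 0L)) abort("divergence is undefined when both strings are empty")
  edit_distance(a, b) / len
}

# Full edit-distance matrix between two string vectors (utils::adist).
edit_matrix <- function(x, y = x) {
  m <- adist(x, y)
  storage.mode(m) <- "integer"
  m
}

# Tie order for consensus columns: gap loses ties; A<C<G<T first, then any
# other character code alphabetically.
.vote_winner <- function(chars) {
  tab <- table(chars)
  nuc <- setdiff(names(tab), "-")
  if (length(nuc) == 0L) return("-")
  ord <- c("A", "C", "G", "T")
  nuc <- nuc[order(match(nuc, ord, nomatch = 5L), nuc)]
  best <- nuc[which.max(tab[nuc])]
  gap <- if ("-" %in% names(tab)) tab[["-"]] else 0L
  if (gap > tab[[best]]) "-" else best
}

#' Consensus of a set of similar nucleotide strings
#'
#' Deterministic center-star consensus: the center string minimizes the total
#' edit distance to all inputs (over a bounded, evenly spaced candidate
#' subset); every other string is globally aligned to the center and the
#' consensus is the column majority. Ties between nucleotides are broken in
#' the fixed order A < C < G < T, and a gap loses ties to any nucleotide.
#' Insertions relative to the center are emitted when present in more than
#' half of the inputs (majority inserted string, ties lexicographic).
#'
#' @param strings Non-empty character vector of similar nucleotide strings.
#' @param max_center_candidates Number of evenly spaced center candidates to
#'   score (bounds the quadratic center search). Default 25.
#' @return A list of class `consensus_result` with elements `consensus`
#'   (character scalar) and `support` (number of input strings).
#' @examples
#' consensus(c("ACGT", "ACGA", "ACGT"))$consensus
#' @export
consensus <- function(strings, max_center_candidates = 25L) {
  if (length(strings) == 0L) abort("consensus of an empty string list is undefined")
  stopifnot(is.character(strings), all(nchar(strings) > 0L))
  n <- length(strings)
  if (n == 1L || length(unique(strings)) == 1L) {
    return(structure(list(consensus = strings[[1L]], support = n),
                     class = "consensus_result"))
  }
  cand <- unique(round(seq(1L, n, length.out = min(n, max_center_candidates))))
  tot <- rowSums(edit_matrix(strings[cand], strings))
  center_idx <- cand[which.min(tot)]
  center <- strings[center_idx]
  lc <- nchar(center)

  votes <- vector("list", lc)          # per center position, character votes
  inserts <- vector("list", lc + 1L)   # slot g = insertion after position g
  for (p in seq_len(lc)) votes[[p]] <- character(0)
  for (g in seq_len(lc + 1L)) inserts[[g]] <- character(0)

  cch <- strsplit(center, "", fixed = TRUE)[[1L]]
  for (s in strings) {
    if (s == center) {
      for (p in seq_len(lc)) votes[[p]] <- c(votes[[p]], cch[p])
      for (g in seq_len(lc + 1L)) inserts[[g]] <- c(inserts[[g]], "")
      next
    }
    al <- cpp_nw_align(center, s)
    sch <- strsplit(s, "", fixed = TRUE)[[1L]]
    last_center <- 0L
    pend <- character(0)
    ins_here <- rep("", lc + 1L)
    for (t in seq_along(al$a)) {
      ca <- al$a[t]; cb <- al$b[t]
      if (is.na(ca)) {
        pend <- c(pend, sch[cb])
      } else {
        if (length(pend) > 0L) {
          ins_here[last_center + 1L] <- paste(pend, collapse = "")
          pend <- character(0)
        }
        votes[[ca]] <- c(votes[[ca]], if (is.na(cb)) "-" else sch[cb])
        last_center <- ca
      }
    }
    if (length(pend) > 0L) ins_here[last_center + 1L] <- paste(pend, collapse = "")
    for (g in seq_len(lc + 1L)) inserts[[g]] <- c(inserts[[g]], ins_here[g])
  }

  out <- character(0)
  for (p in 0:lc) {
    if (p > 0L) {
      w <- .vote_winner(votes[[p]])
      if (w != "-") out <- c(out, w)
    }
    ins <- inserts[[p + 1L]]
    nonempty <- ins[nzchar(ins)]
    if (length(nonempty) > n / 2) {
      tab <- sort(table(nonempty), decreasing = TRUE)
      winners <- names(tab)[tab == tab[[1L]]]
      out <- c(out, sort(winners)[1L])
    }
  }
  structure(list(consensus = paste(out, collapse = ""), support = n),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus of", x$support, "strings (", nchar(x$consensus), "bp):\n")
  cat(x$consensus, "\n")
  invisible(x)
}
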