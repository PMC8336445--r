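# Fixture builders and independent oracles used across the suite.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitutions at exactly n distinct positions
mutate_subs <- function(seq, n_sub) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), min(n_sub, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# per-bp substitution noise
mutate_rate <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- which(runif(length(ch)) < rate)
  for (p in idx) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# --- independent Needleman-Wunsch score (match +1, mismatch/indel -1) -----
nw_score <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  la <- length(ca); lb <- length(cb)
  D <- matrix(0L, la + 1L, lb + 1L)
  D[, 1L] <- 0L:la * -1L
  D[1L, ] <- 0L:lb * -1L
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      D[i + 1L, j + 1L] <- max(
        D[i, j] + if (ca[i] == cb[j]) 1L else -1L,
        D[i, j + 1L] - 1L,
        D[i + 1L, j] - 1L)
    }
  }
  D[la + 1L, lb + 1L]
}

# --- brute-force tiling oracle: best total score over all tilings ---------
# Exhaustive over all block boundaries via prefix maximization; independent
# of the package's joint DP (per-substring global alignment + prefix scan).
oracle_tiling_score <- function(seq, monomers) {
  n <- nchar(seq)
  best <- c(0, rep(-Inf, n))
  for (i in seq_len(n)) {
    for (j in 0:(i - 1L)) {
      if (!is.finite(best[j + 1L])) next
      sub <- substr(seq, j + 1L, i)
      sc <- max(vapply(monomers, function(m) nw_score(sub, m), numeric(1)))
      cand <- best[j + 1L] + sc
      if (cand > best[i + 1L]) best[i + 1L] <- cand
    }
  }
  best[n + 1L]
}

# --- brute-force block graph (all pairs, utils::adist) --------------------
oracle_block_graph_edges <- function(seqs, threshold) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  dm <- adist(seqs, seqs) / outer(nchar(seqs), nchar(seqs), pmax)
  which(upper.tri(dm) & dm < threshold, arr.ind = TRUE)
}

# simulated tandem fixture returning both array and per-block truth strings
make_tandem <- function(monomers, pattern, n_units, rate = 0, seed = 1L) {
  withr::with_seed(seed, {
    blocks <- character(0)
    ids <- character(0)
    for (u in seq_len(n_units)) {
      for (k in pattern) {
        blocks <- c(blocks, if (rate > 0) mutate_rate(monomers[k], rate)
                    else monomers[k])
        ids <- c(ids, names(monomers)[k])
      }
    }
    list(seq = paste(blocks, collapse = ""), block_seqs = blocks, ids = ids)
  })
}

table2_alphabet <- c(LETTERS[1:14], letters[1:8], "LINE")

table2_hors <- function() {
  readr::read_tsv(system.file("extdata", "cenx_hors.tsv", package = "horinfer"),
                  show_col_types = FALSE)
}

table2_decomposition_text <- function() {
  readLines(system.file("extdata", "cenx_hor_decomposition.txt",
                        package = "horinfer"))
}
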