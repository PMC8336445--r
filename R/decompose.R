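#' Normalise a monomer set to a tibble
#'
#' Accepts a named character vector of sequences or a data frame with `id`
#' and `seq` columns; returns a tibble with columns `id`, `seq` and
#' `is_nonmonomeric` (strings added to the alphabet to absorb non-monomeric
#' regions, e.g. transposon insertions).
#'
#' @param x Named character vector or data frame of monomers.
#' @return A tibble with columns `id`, `seq`, `is_nonmonomeric`.
#' @export
as_monomer_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    out <- as_tibble(x)
    if (!"is_nonmonomeric" %in% names(out)) out$is_nonmonomeric <- FALSE
    out <- out[, c("id", "seq", "is_nonmonomeric",
                   setdiff(names(out), c("id", "seq", "is_nonmonomeric")))]
  } else {
    stopifnot(is.character(x))
    ids <- names(x) %||% paste0("m", sprintf("%03d", seq_along(x)))
    if (is.null(names(x)) || any(!nzchar(ids))) {
      ids[!nzchar(ids)] <- paste0("m", sprintf("%03d", which(!nzchar(ids))))
    }
    out <- tibble(id = ids, seq = toupper(unname(x)), is_nonmonomeric = FALSE)
  }
  if (anyDuplicated(out$id)) abort("duplicate monomer ids")
  if (any(nchar(out$seq) == 0L)) abort("empty monomer sequence")
  out$seq <- toupper(out$seq)
  out
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decompose a satellite array into monomeric blocks
#'
#' Dynamic program over the sequence: the best-scoring tiling of the array by
#' consecutive blocks, each globally aligned to one monomer (per-position
#' score: match +1, mismatch/indel -1; block boundaries free). For every
#' block the divergence to its most similar (`div1`) and second-most similar
#' (`div2`) monomer is reported, and the block is classified as `resolved`,
#' `unresolved` or `non_monomeric` against the thresholds in `params`.
#'
#' @param sequence A single nucleotide string (optionally named; the name is
#'   used as `seq_id`).
#' @param monomers Monomer set (see [as_monomer_tbl()]).
#' @param params A [decomposition_params()] object.
#' @param seq_id Identifier for the sequence; defaults to the name of
#'   `sequence` or `"seq1"`.
#' @return A tibble of blocks with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `best_monomer`, `second_monomer`, `div1`, `div2`, `status`
#'   and `seq` (the block sequence). Blocks tile the input exactly.
#' @export
decompose <- function(sequence, monomers, params = decomposition_params(),
                      seq_id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_id <- seq_id %||% names(sequence) %||% "seq1"
  sequence <- toupper(unname(sequence))
  if (nchar(sequence) == 0L) abort("empty sequence")
  mon <- as_monomer_tbl(monomers)
  if (nrow(mon) == 0L) abort("empty monomer set")
  cand <- mon
  if (isTRUE(params$allow_reverse)) {
    rc <- mon
    rc$id <- paste0(mon$id, "'")
    rc$seq <- reverse_complement(mon$seq)
    cand <- bind_rows(mon, rc)
  }
  # fixed lexicographic order of ids: deterministic tie-breaking
  cand <- cand[order(cand$id, method = "radix"), ]
  res <- cpp_tile_decompose(sequence, cand$seq, 1L, -1L, -1L)
  blk_seq <- substring(sequence, res$start + 1L, res$end)
  dmat <- edit_matrix(blk_seq, cand$seq)
  nb <- length(blk_seq)
  best_i <- integer(nb); second_i <- rep(NA_integer_, nb)
  for (i in seq_len(nb)) {
    o <- order(dmat[i, ], method = "radix")  # ties -> earliest id
    best_i[i] <- o[1L]
    if (length(o) > 1L) second_i[i] <- o[2L]
  }
  dv <- function(bi, i) dmat[cbind(i, bi)] /
    pmax(nchar(blk_seq), nchar(cand$seq)[bi])
  div1 <- dv(best_i, seq_len(nb))
  div2 <- ifelse(is.na(second_i), NA_real_, dv(second_i, seq_len(nb)))
  out <- tibble(
    seq_id = seq_id,
    start = as.integer(res$start),
    end = as.integer(res$end),
    best_monomer = cand$id[best_i],
    second_monomer = cand$id[second_i],
    div1 = div1,
    div2 = div2,
    status = classify_block(div1, params),
    seq = blk_seq
  )
  attr(out, "alignment_score") <- res$score
  attr(out, "monomer_tbl") <- cand
  out
}

#' Classify blocks by divergence thresholds
#'
#' A block is `resolved` if `div1 < max_resolved_divergence`, `non_monomeric`
#' if `div1 > max_divergence`, and `unresolved` otherwise.
#'
#' @param div1 Numeric vector of best-monomer divergences, or a block tibble
#'   with a `div1` column.
#' @param params A [decomposition_params()] object.
#' @return Character vector of statuses.
#' @export
classify_block <- function(div1, params = decomposition_params()) {
  if (is.data.frame(div1)) div1 <- div1$div1
  stopifnot(is.numeric(div1))
  dplyr::case_when(
    div1 < params$max_resolved_divergence ~ "resolved",
    div1 > params$max_divergence ~ "non_monomeric",
    TRUE ~ "unresolved"
  )
}

#' Translate blocks into a monostring
#'
#' Rewrites the array over the monomer alphabet: resolved and unresolved
#' blocks contribute their best monomer's symbol; non-monomeric blocks
#' contribute the `?` token (or, for alphabet members flagged
#' non-monomeric, their own id, which downstream HOR inference treats like
#' the token). A positional back-map to blocks is retained.
#'
#' @param blocks Block tibble from [decompose()].
#' @param monomers Optional monomer table (defaults to the one attached to
#'   `blocks`); its `is_nonmonomeric` flags drive symbol classification.
#' @return A `mono_string` object.
#' @export
to_monostring <- function(blocks, monomers = NULL) {
  mon <- monomers %||% attr(blocks, "monomer_tbl")
  if (!is.null(mon)) mon <- as_monomer_tbl(mon)
  if (nrow(blocks) == 0L) {
    return(mono_string(character(0), alphabet = mon, blocks = blocks))
  }
  sym <- ifelse(blocks$status == "non_monomeric", NONMONOMERIC_TOKEN,
                blocks$best_monomer)
  mono_string(sym, alphabet = mon, blocks = blocks)
}

#' Construct a monostring object
#'
#' @param symbols Character vector of monomer symbols (the `?` token marks
#'   non-monomeric blocks).
#' @param alphabet Optional monomer table ([as_monomer_tbl()]).
#' @param blocks Optional block tibble back-map (one row per symbol).
#' @return An object of class `mono_string`.
#' @export
mono_string <- function(symbols, alphabet = NULL, blocks = NULL) {
  stopifnot(is.character(symbols))
  if (!is.null(blocks) && nrow(blocks) != length(symbols)) {
    abort("blocks back-map must have one row per symbol")
  }
  structure(list(symbols = symbols, alphabet = alphabet, blocks = blocks),
            class = "mono_string")
}

#' @export
print.mono_string <- function(x, ...) {
  cat("<mono_string> ", length(x$symbols), " symbols over ",
      length(setdiff(unique(x$symbols), NONMONOMERIC_TOKEN)),
      " monomer symbols\n", sep = "")
  preview <- paste(head(x$symbols, 30L), collapse = " ")
  cat(preview, if (length(x$symbols) > 30L) "..." else "", "\n")
  invisible(x)
}

#' @export
as.character.mono_string <- function(x, ...) x$symbols

#' Absorb non-monomeric regions into the alphabet
#'
#' Runs a first decomposition, extracts maximal runs of non-monomeric blocks
#' as strings, clusters them by single-linkage at divergence
#' `max_resolved_divergence`, adds each cluster consensus to the alphabet
#' flagged non-monomeric, and re-decomposes. Arrays without non-monomeric
#' blocks are returned unchanged.
#'
#' @inheritParams decompose
#' @return A list with `monomers` (the possibly extended monomer tibble) and
#'   `blocks` (the final block tibble).
#' @export
augment_with_nonmonomeric <- function(sequence, monomers,
                                      params = decomposition_params(),
                                      seq_id = NULL) {
  mon <- as_monomer_tbl(monomers)
  first <- decompose(sequence, mon, params, seq_id = seq_id)
  nm <- first$status == "non_monomeric"
  if (!any(nm)) return(list(monomers = mon, blocks = first))
  r <- rle(nm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  segs <- vapply(keep, function(k) {
    paste0(substring(toupper(unname(sequence)),
                     first$start[starts[k]] + 1L, first$end[ends[k]]),
           collapse = "")
  }, character(1))
  # single-linkage clustering of the extracted strings
  ns <- length(segs)
  memb <- seq_len(ns)
  if (ns > 1L) {
    dm <- edit_matrix(segs, segs) / outer(nchar(segs), nchar(segs), pmax)
    g <- igraph::graph_from_adjacency_matrix(
      dm <= params$max_resolved_divergence, mode = "undirected", diag = FALSE)
    memb <- igraph::components(g)$membership
  }
  added <- purrr::map_chr(split(segs, memb), function(s) consensus(s)$consensus)
  ext <- bind_rows(mon, tibble(
    id = paste0("nm", sprintf("%02d", seq_along(added))),
    seq = unname(added),
    is_nonmonomeric = TRUE
  ))
  blocks <- decompose(sequence, ext, params, seq_id = seq_id)
  list(monomers = ext, blocks = blocks)
}
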