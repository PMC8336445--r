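#' Build the directed monomer-graph of a monostring
#'
#' Vertices are monomers; a directed edge (M, M') with weight w records that
#' M' immediately follows M w times in the monostring. Pairs separated by a
#' non-monomeric block (the `?` token or an alphabet string flagged
#' non-monomeric) contribute no edge.
#'
#' @param monostring A `mono_string` (or character vector of symbols).
#' @return An object of class `monomer_graph`: list with `vertices`
#'   (character) and `edges` (tibble `from`, `to`, `weight`).
#' @export
build_monomer_graph <- function(monostring) {
  sym <- ss_flat(monostring)
  nonmono <- NONMONOMERIC_TOKEN
  if (inherits(monostring, "mono_string") && !is.null(monostring$alphabet)) {
    nonmono <- c(nonmono,
                 monostring$alphabet$id[monostring$alphabet$is_nonmonomeric])
    vertices <- monostring$alphabet$id[!monostring$alphabet$is_nonmonomeric]
  } else {
    vertices <- setdiff(unique(sym), nonmono)
  }
  n <- length(sym)
  edges <- tibble(from = character(0), to = character(0), weight = integer(0))
  if (n >= 2L) {
    from <- sym[-n]; to <- sym[-1L]
    ok <- !(from %in% nonmono) & !(to %in% nonmono)
    if (any(ok)) {
      edges <- tibble(from = from[ok], to = to[ok]) |>
        dplyr::count(.data$from, .data$to, name = "weight") |>
        arrange(.data$from, .data$to)
      edges$weight <- as.integer(edges$weight)
    }
  }
  structure(list(vertices = vertices, edges = edges), class = "monomer_graph")
}

#' @export
print.monomer_graph <- function(x, ...) {
  cat("<monomer_graph> ", length(x$vertices), " monomers, ", nrow(x$edges),
      " edges (total weight ", sum(x$edges$weight), ")\n", sep = "")
  invisible(x)
}

#' Generate an i-shifted monomer-set
#'
#' Every monomer-graph edge (M, M') yields a candidate shifted monomer: the
#' i-suffix of M concatenated with the (|M'| - i)-prefix of M'. Candidates
#' are then merged by single-linkage whenever their divergence does not
#' exceed `merge_threshold`; each merged monomer is the weighted consensus
#' of its member candidates (weights = source-edge weights) and is labelled
#' by its source edges ("X-Y").
#'
#' @param monostring A `mono_string` over `monomers`.
#' @param monomers The monomer set used to produce `monostring`.
#' @param i Shift in nucleotides; must satisfy `0 < i < min monomer length`.
#' @param merge_threshold Merge divergence (default half the standard 5%
#'   resolved-divergence threshold).
#' @return A tibble of shifted monomers: `id`, `seq`, `sources`, `weight`;
#'   attribute `edge_map` maps "M|M'" source edges to shifted ids.
#' @export
shift_monomers <- function(monostring, monomers, i, merge_threshold = 0.025) {
  mon <- as_monomer_tbl(monomers)
  if (!(i > 0L && i < min(nchar(mon$seq)))) {
    abort("shift must satisfy 0 < i < min monomer length")
  }
  mg <- build_monomer_graph(monostring)
  ed <- mg$edges
  if (nrow(ed) == 0L) {
    out <- tibble(id = character(0), seq = character(0),
                  sources = character(0), weight = integer(0))
    attr(out, "edge_map") <- character(0)
    return(out)
  }
  seq_of <- setNames(mon$seq, mon$id)
  cand <- vapply(seq_len(nrow(ed)), function(k) {
    m1 <- seq_of[[ed$from[k]]]; m2 <- seq_of[[ed$to[k]]]
    paste0(substring(m1, nchar(m1) - i + 1L, nchar(m1)),
           substring(m2, 1L, nchar(m2) - i))
  }, character(1))
  labels <- paste0(ed$from, "-", ed$to)
  # single-linkage merge under the divergence threshold
  nc <- length(cand)
  memb <- seq_len(nc)
  if (nc > 1L) {
    dm <- edit_matrix(cand, cand) / outer(nchar(cand), nchar(cand), pmax)
    g <- igraph::graph_from_adjacency_matrix(dm <= merge_threshold,
                                             mode = "undirected", diag = FALSE)
    memb <- igraph::components(g)$membership
  }
  groups <- split(seq_len(nc), memb)
  rows <- purrr::imap(groups, function(idx, grp) {
    reps <- rep(cand[idx], times = pmin(ed$weight[idx], 50L))
    tibble(seq = consensus(evenly_spaced(reps, 100L))$consensus,
           sources = paste(labels[idx], collapse = ";"),
           weight = sum(ed$weight[idx]))
  })
  out <- bind_rows(rows)
  out <- dplyr::bind_cols(
    tibble(id = paste0("sh", sprintf("%02d", seq_len(nrow(out))))), out)
  edge_map <- setNames(out$id[match(memb, as.integer(names(groups)))],
                       paste0(ed$from, "|", ed$to))
  attr(out, "edge_map") <- edge_map
  out
}

#' Monomer-graph on a shifted monomer-set
#'
#' For every triple of consecutive monomers (M, M', M'') in the monostring
#' (triples spanning a non-monomeric block are skipped), adds an edge
#' between the shifted monomers derived from edges (M, M') and (M', M'');
#' edge weights count such triples, mapped through candidate merging.
#'
#' @param monostring The `mono_string` the shifted set was derived from.
#' @param shifted A shifted monomer tibble from [shift_monomers()].
#' @return A `monomer_graph` on the shifted monomer ids.
#' @export
build_shifted_monomer_graph <- function(monostring, shifted) {
  edge_map <- attr(shifted, "edge_map")
  if (is.null(edge_map)) abort("shifted set lacks its edge_map attribute")
  sym <- ss_flat(monostring)
  nonmono <- NONMONOMERIC_TOKEN
  if (inherits(monostring, "mono_string") && !is.null(monostring$alphabet)) {
    nonmono <- c(nonmono,
                 monostring$alphabet$id[monostring$alphabet$is_nonmonomeric])
  }
  n <- length(sym)
  edges <- tibble(from = character(0), to = character(0), weight = integer(0))
  if (n >= 3L) {
    a <- sym[1:(n - 2L)]; b <- sym[2:(n - 1L)]; c_ <- sym[3:n]
    ok <- !(a %in% nonmono) & !(b %in% nonmono) & !(c_ %in% nonmono)
    if (any(ok)) {
      from <- edge_map[paste0(a[ok], "|", b[ok])]
      to <- edge_map[paste0(b[ok], "|", c_[ok])]
      keep <- !is.na(from) & !is.na(to)
      if (any(keep)) {
        edges <- tibble(from = unname(from[keep]), to = unname(to[keep])) |>
          dplyr::count(.data$from, .data$to, name = "weight") |>
          arrange(.data$from, .data$to)
        edges$weight <- as.integer(edges$weight)
      }
    }
  }
  structure(list(vertices = shifted$id, edges = edges),
            class = "monomer_graph")
}
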