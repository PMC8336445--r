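#' Build the HOR-graph
#'
#' Undirected graph on HOR definitions (possibly pooled across several
#' arrays): an edge connects two HORs whose expansions, flattened to monomer
#' multisets, share at least one monomer. Within each connected component
#' the HOR with the maximal count is the primary HOR (ties broken by the
#' lexicographically smallest id); all others are secondary.
#'
#' @param hors HOR definition tibble with columns `id`, `expansion` (list of
#'   symbol vectors, or a character column of single-character symbols) and
#'   `count`. Expansions may reference other HOR ids in the table.
#' @return An object of class `hor_graph`: list with `vertices` (tibble:
#'   `id`, `count`, `n_monomers`, `component`, `is_primary`) and `edges`
#'   (tibble: `from`, `to`, `shared` monomer count).
#' @export
build_hor_graph <- function(hors) {
  stopifnot(all(c("id", "expansion", "count") %in% names(hors)))
  hors <- as_tibble(hors)
  if (!is.list(hors$expansion)) {
    hors$expansion <- lapply(hors$expansion,
                             function(x) strsplit(x, "", fixed = TRUE)[[1L]])
  }
  n <- nrow(hors)
  monoset <- lapply(seq_len(n), function(i) {
    flat <- expand_decomposition(symbol_string(hors$expansion[[i]]), hors)
    unique(setdiff(flat, c(hors$id, NONMONOMERIC_TOKEN)))
  })
  edges <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sh <- length(intersect(monoset[[i]], monoset[[j]]))
        if (sh > 0L) {
          edges[[length(edges) + 1L]] <-
            tibble(from = hors$id[i], to = hors$id[j], shared = sh)
        }
      }
    }
  }
  edges <- if (length(edges)) bind_rows(edges) else
    tibble(from = character(0), to = character(0), shared = integer(0))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = hors$id))
  memb <- igraph::components(g)$membership[hors$id]
  vertices <- tibble(
    id = hors$id,
    count = hors$count,
    n_monomers = lengths(monoset),
    component = as.integer(memb)
  )
  vertices <- vertices |>
    group_by(.data$component) |>
    mutate(is_primary = rank_primary(.data$count, .data$id)) |>
    ungroup()
  structure(list(vertices = vertices, edges = edges), class = "hor_graph")
}

# TRUE for the single max-count vertex, ties by smallest id
rank_primary <- function(count, id) {
  best <- which(count == max(count))
  if (length(best) > 1L) best <- best[order(id[best], method = "radix")][1L]
  seq_along(count) == best
}

#' @export
print.hor_graph <- function(x, ...) {
  nc <- length(unique(x$vertices$component))
  cat("<hor_graph> ", nrow(x$vertices), " HORs, ", nrow(x$edges),
      " edges, ", nc, " component", if (nc != 1L) "s", "\n", sep = "")
  prim <- x$vertices[x$vertices$is_primary, ]
  cat("primary HORs: ",
      paste(sprintf("%s (count %d)", prim$id, prim$count), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
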