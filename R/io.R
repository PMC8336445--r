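#' Read a FASTA file
#'
#' Sequences are uppercased; duplicate ids are rejected.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A named character vector of sequences (names = record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) {
                  abort(paste0("malformed FASTA in ", path, ": ",
                               conditionMessage(e)))
                })
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1L]))
  }
  setNames(toupper(as.character(x)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or monomer tibble, whose statistics
#'   columns are folded into the headers as `id|class|count|radius|separation`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.data.frame(seqs)) {
    mon <- seqs
    hdr <- mon$id
    if (all(c("freq_class", "count", "radius", "separation") %in% names(mon))) {
      hdr <- paste(mon$id, mon$freq_class, mon$count, mon$radius,
                   mon$separation, sep = "|")
    }
    seqs <- setNames(mon$seq, hdr)
  }
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write a block decomposition as TSV
#'
#' One row per block; 0-based half-open coordinates; divergences in percent
#' with two decimals. [read_decomposition_tsv()] restores the values.
#'
#' @param blocks Block tibble from [decompose()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decomposition_tsv <- function(blocks, path) {
  out <- tibble(
    seq_id = blocks$seq_id,
    monomer_id = blocks$best_monomer,
    start = blocks$start,
    end = blocks$end,
    div1_pct = sprintf("%.2f", 100 * blocks$div1),
    second_monomer_id = blocks$second_monomer,
    div2_pct = ifelse(is.na(blocks$div2), "",
                      sprintf("%.2f", 100 * blocks$div2)),
    status = blocks$status
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a block decomposition TSV
#'
#' @param path Path written by [write_decomposition_tsv()].
#' @return A block tibble (without the `seq` column).
#' @export
read_decomposition_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         seq_id = "c", monomer_id = "c", start = "i",
                         end = "i", div1_pct = "d", second_monomer_id = "c",
                         div2_pct = "d", status = "c"))
  tibble(
    seq_id = x$seq_id, start = x$start, end = x$end,
    best_monomer = x$monomer_id, second_monomer = x$second_monomer_id,
    div1 = x$div1_pct / 100, div2 = x$div2_pct / 100, status = x$status
  )
}

#' Write non-monomeric regions as BED
#'
#' Maximal runs of non-monomeric blocks, 0-based half-open.
#'
#' @param blocks Block tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nonmonomeric_bed <- function(blocks, path) {
  nm <- blocks$status == "non_monomeric"
  rows <- list()
  if (any(nm)) {
    r <- rle(nm)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = blocks$seq_id[starts[k]],
        start = blocks$start[starts[k]],
        end = blocks$end[ends[k]])
    }
  }
  df <- if (length(rows)) bind_rows(rows) else
    tibble(chrom = character(0), start = integer(0), end = integer(0))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Export a graph as a DOT file
#'
#' @param graph A `monomer_graph`, `block_graph` or `hor_graph` (anything
#'   with an `edges` tibble `from`/`to` and optional `weight`).
#' @param path Output path.
#' @param directed Emit a digraph.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(graph, path, directed = inherits(graph, "monomer_graph")) {
  e <- graph$edges
  verts <- if (!is.null(graph$vertices)) {
    if (is.data.frame(graph$vertices)) graph$vertices$id else graph$vertices
  } else unique(c(e$from, e$to))
  arrow <- if (directed) " -> " else " -- "
  lines <- c(if (directed) "digraph G {" else "graph G {",
             paste0("  \"", verts, "\";"),
             vapply(seq_len(nrow(e)), function(k) {
               lab <- if (!is.null(e$weight)) {
                 paste0(" [label=", e$weight[k], "]")
               } else ""
               paste0("  \"", e$from[k], "\"", arrow, "\"", e$to[k], "\"",
                      lab, ";")
             }, character(1)),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Format a symbol string in the printed run-length dialect
#'
#' Degrees are written as `X^n^`; multi-character symbols are wrapped in
#' underscores (`_LINE_`).
#'
#' @param s A `symbol_string` (or flat symbol vector).
#' @return A single string.
#' @export
format_symbol_string <- function(s) {
  if (!inherits(s, "symbol_string")) s <- run_length_encode(.as_symbols(s))
  if (length(s$symbols) == 0L) return("")
  sym <- ifelse(nchar(s$symbols) > 1L, paste0("_", s$symbols, "_"), s$symbols)
  paste0(sym, ifelse(s$degrees > 1L, paste0("^", s$degrees, "^"), ""),
         collapse = "")
}

#' Parse a run-length HOR string
#'
#' Accepts the printed dialect: single-character symbols, powers as `X^n^`
#' or caret-free `X114`, and multi-character symbols wrapped in underscores
#' (`_LINE_`). Every symbol must be resolvable against `alphabet` (plus the
#' `?` token); an unknown symbol is an error naming it.
#'
#' @param text The run-length HOR string.
#' @param alphabet Character vector of admissible symbols.
#' @return A `symbol_string`.
#' @examples
#' parse_hor_string("AB^2^CA^3^D", c("A", "B", "C", "D"))
#' @export
parse_hor_string <- function(text, alphabet) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\s", "", text)
  symbols <- character(0); degrees <- integer(0)
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "_") {
      j <- regexpr("_", substr(text, i + 1L, n), fixed = TRUE)
      if (j == -1L) abort("unterminated '_' symbol in HOR string")
      sym <- substr(text, i + 1L, i + j - 1L)
      i <- i + j + 1L
    } else {
      sym <- ch
      i <- i + 1L
    }
    deg <- 1L
    if (i <= n && substr(text, i, i) == "^") {
      m <- regmatches(substr(text, i, n), regexpr("^\\^[0-9]+\\^?", substr(text, i, n)))
      num <- gsub("\\^", "", m)
      if (!nzchar(num)) abort("malformed power in HOR string")
      deg <- as.integer(num)
      i <- i + nchar(m)
    } else if (i <= n && grepl("^[0-9]", substr(text, i, i))) {
      m <- regmatches(substr(text, i, n), regexpr("^[0-9]+", substr(text, i, n)))
      deg <- as.integer(m)
      i <- i + nchar(m)
    }
    if (!(sym %in% alphabet || sym == NONMONOMERIC_TOKEN)) {
      abort(paste0("unknown symbol in HOR string: '", sym, "'"))
    }
    symbols <- c(symbols, sym); degrees <- c(degrees, deg)
  }
  symbol_string(symbols, degrees)
}

#' Write a run manifest
#'
#' Records input paths, parameter values, package version, seed, and an MD5
#' checksum for every emitted file.
#'
#' @param outputs Character vector of emitted file paths.
#' @param inputs Character vector of input file paths.
#' @param params A (possibly nested) list of parameter values.
#' @param seed Integer seed used for the run (or `NULL`).
#' @param path Manifest output path (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(outputs, inputs = character(0), params = list(),
                           seed = NULL, path) {
  manifest <- list(
    tool = "horinfer",
    version = as.character(utils::packageVersion("horinfer")),
    seed = seed,
    inputs = as.list(inputs),
    params = lapply(unclass(params), function(x) x),
    outputs = lapply(outputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write the monomer-inference iteration log as TSV
#'
#' Columns: iteration, resolved / unresolved / non-monomeric block counts,
#' largest block-graph component, radius and separation (to previously
#' generated monomers) of the new monomer, and its length.
#'
#' @param log Iteration log tibble from [generate_monomers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_iteration_log <- function(log, path) {
  readr::write_tsv(log, path, na = "-")
  invisible(path)
}
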