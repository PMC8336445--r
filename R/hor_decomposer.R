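# rle length of an encoded (single code point per symbol) string
.enc_rle_len <- function(enc) {
  if (nchar(enc) == 0L) return(0L)
  rle_len(utf8ToInt(enc))
}

# Substitute leftmost non-overlapping occurrences in an encoded string with
# a single placeholder code point.
.enc_substitute <- function(enc, enc_h, placeholder) {
  starts <- .leftmost_starts(enc, enc_h)
  if (length(starts) == 0L) return(enc)
  k <- nchar(enc_h)
  pieces <- character(0)
  prev <- 1L
  for (st in starts) {
    pieces <- c(pieces, substr(enc, prev, st - 1L), placeholder)
    prev <- st + k
  }
  pieces <- c(pieces, substr(enc, prev, nchar(enc)))
  paste(pieces, collapse = "")
}

#' Select the next HOR candidate
#'
#' Among substrings h of the symbol string with at most `max_length` symbols,
#' occurrence count passing `min_count`, weight passing `min_weight`, at
#' least two distinct symbols (non-trivial) and -- unless
#' `initial_alphabet = NULL` -- at least one symbol from the initial monomer
#' alphabet, returns one minimizing the run-length-encoded length of the
#' h-substitution |S(h)*|. Ties: shortest h, then lexicographically smallest
#' expansion. Comparisons are strict ("exceeds") unless `inclusive = TRUE`
#' (the superHOR setting).
#'
#' @param s Symbol string (flat character vector, `symbol_string`,
#'   `mono_string` or plain single-character string).
#' @param params A [hor_params()] object.
#' @param initial_alphabet Symbols counting as original monomers, or `NULL`
#'   to drop the monomer-containment requirement.
#' @param inclusive Use `>=` instead of `>` for count/weight thresholds.
#' @param min_count,min_weight Threshold overrides (default from `params`).
#' @param forbidden Symbols a candidate may not contain (the non-monomeric
#'   token and alphabet strings flagged non-monomeric).
#' @return `NULL` if no candidate qualifies, else a list with `h` (symbol
#'   vector), `count`, `weight` and `rle_after`.
#' @export
select_hor <- function(s, params = hor_params(), initial_alphabet = NULL,
                       inclusive = FALSE,
                       min_count = params$min_count,
                       min_weight = params$min_weight,
                       forbidden = NONMONOMERIC_TOKEN) {
  sv <- .as_symbols(s)
  n <- length(sv)
  if (n < 2L) return(NULL)
  alpha <- unique(sv)
  enc <- sym_encode(sv, alpha)
  rle_before <- rle_len(sv)
  placeholder <- intToUtf8(SYM_BASE)
  bad_chars <- if (length(intersect(forbidden, alpha)))
    strsplit(sym_encode(intersect(forbidden, alpha), alpha), "")[[1L]] else character(0)
  init_chars <- if (!is.null(initial_alphabet) && length(intersect(initial_alphabet, alpha)))
    strsplit(sym_encode(intersect(initial_alphabet, alpha), alpha), "")[[1L]] else character(0)
  if (!is.null(initial_alphabet) && length(init_chars) == 0L) return(NULL)

  need <- if (inclusive) min_count else min_count + 1L
  cands <- character(0)
  for (len in 2L:min(params$max_length, n)) {
    subs <- substring(enc, 1L:(n - len + 1L), len:n)
    tab <- table(subs)
    cands <- c(cands, names(tab)[tab >= need])  # plain count bounds the
  }                                             # non-overlapping count
  cands <- unique(cands)
  if (length(cands) == 0L) return(NULL)

  best <- NULL
  for (hc in cands) {
    chars <- strsplit(hc, "", fixed = TRUE)[[1L]]
    if (length(unique(chars)) < 2L) next
    if (length(bad_chars) && any(chars %in% bad_chars)) next
    if (!is.null(initial_alphabet) && !any(chars %in% init_chars)) next
    starts <- .leftmost_starts(enc, hc)
    cnt <- length(starts)
    if (if (inclusive) cnt < min_count else cnt <= min_count) next
    res <- .enc_substitute(enc, hc, placeholder)
    rle_after <- .enc_rle_len(res)
    w <- rle_before - rle_after
    if (if (inclusive) w < min_weight else w <= min_weight) next
    hv <- sym_decode(hc, alpha)
    key <- list(rle_after = rle_after, len = length(hv),
                expkey = paste(hv, collapse = "\x1f"))
    if (is.null(best) ||
        key$rle_after < best$rle_after ||
        (key$rle_after == best$rle_after &&
           (key$len < best$len ||
              (key$len == best$len && key$expkey < best$expkey)))) {
      best <- c(key, list(h = hv, count = cnt, weight = w))
    }
  }
  if (is.null(best)) return(NULL)
  list(h = best$h, count = best$count, weight = best$weight,
       rle_after = best$rle_after)
}

.fresh_hor_id <- function(prefix, k, taken) {
  id <- sprintf("%s%02d", prefix, k)
  while (id %in% taken) id <- paste0(id, "x")
  id
}

#' Greedy HOR decomposition of a monostring
#'
#' Iteratively selects a recurrent heavy non-trivial substring containing at
#' least one monomer symbol that minimizes the run-length-encoded length of
#' its substitution, substitutes it by a new HOR symbol, and stops when no
#' such substring remains. Canonical HORs supplied via `canonical` are
#' substituted first in the given order, exempt from the count/weight
#' thresholds, and retained in the output even at count 0. The decomposition
#' is lossless: expanding every HOR symbol and degree reconstructs the input
#' monostring exactly.
#'
#' @param monostring A `mono_string`, `symbol_string`, character vector of
#'   symbols, or plain single-character string.
#' @param params A [hor_params()] object.
#' @param canonical Optional named list of canonical HOR expansions (each a
#'   symbol vector or plain single-character string); names are their ids.
#' @return An object of class `hor_decomposition`: list with `hors` (tibble:
#'   `id`, `expansion` list-column, `n_monomers`, `count`, `weight`,
#'   `n_blocks_final`, `freq_class`, `is_super`, `is_canonical`),
#'   `decomposition` (run-length `symbol_string`), `log` (per-iteration
#'   bookkeeping incl. the score identity columns) and `input` (the original
#'   flat monostring).
#' @export
hor_decompose <- function(monostring, params = hor_params(), canonical = NULL) {
  sv <- .as_symbols(monostring)
  if (inherits(monostring, "mono_string") && !is.null(monostring$alphabet)) {
    init_alpha <- monostring$alphabet$id[!monostring$alphabet$is_nonmonomeric]
    forbidden <- c(NONMONOMERIC_TOKEN,
                   monostring$alphabet$id[monostring$alphabet$is_nonmonomeric])
  } else {
    init_alpha <- setdiff(unique(sv), NONMONOMERIC_TOKEN)
    forbidden <- NONMONOMERIC_TOKEN
  }
  s0 <- sv
  hors <- list()
  log <- list()
  taken <- unique(c(sv, names(canonical)))

  record <- function(id, hv, cnt, w, canonical_flag) {
    tibble(id = id, expansion = list(hv),
           n_monomers = NA_integer_, count = cnt, weight = w,
           is_super = FALSE, is_canonical = canonical_flag)
  }

  if (!is.null(canonical)) {
    if (is.null(names(canonical)) || any(!nzchar(names(canonical)))) {
      abort("canonical HORs must be a named list")
    }
    for (id in names(canonical)) {
      hv <- .as_symbols(canonical[[id]])
      rb <- rle_len(sv)
      cnt <- count_nonoverlapping(sv, hv)$count
      out <- if (cnt > 0L) substitute_symbols(sv, hv, id) else sv
      w <- rb - rle_len(out)
      log[[length(log) + 1L]] <- tibble(
        id = id, n_before = length(sv), rle_before = rb, count = cnt,
        h_len = length(hv), n_after = length(out), rle_after = rle_len(out),
        weight = w)
      sv <- out
      hors[[length(hors) + 1L]] <- record(id, hv, cnt, w, TRUE)
    }
  }

  k <- 0L
  repeat {
    sel <- select_hor(sv, params, initial_alphabet = init_alpha,
                      inclusive = FALSE, forbidden = forbidden)
    if (is.null(sel)) break
    k <- k + 1L
    id <- .fresh_hor_id("h", k, taken)
    taken <- c(taken, id)
    rb <- rle_len(sv)
    out <- substitute_symbols(sv, sel$h, id)
    log[[length(log) + 1L]] <- tibble(
      id = id, n_before = length(sv), rle_before = rb, count = sel$count,
      h_len = length(sel$h), n_after = length(out),
      rle_after = rle_len(out), weight = sel$weight)
    sv <- out
    hors[[length(hors) + 1L]] <- record(id, sel$h, sel$count, sel$weight, FALSE)
  }

  hors <- if (length(hors)) bind_rows(hors) else
    tibble(id = character(0), expansion = list(), n_monomers = integer(0),
           count = integer(0), weight = integer(0), is_super = logical(0),
           is_canonical = logical(0))
  dec <- run_length_encode(sv)
  if (nrow(hors)) {
    defs <- hors
    hors$n_monomers <- vapply(seq_len(nrow(hors)), function(i) {
      length(expand_decomposition(symbol_string(hors$expansion[[i]]), defs))
    }, integer(1))
    hors$n_blocks_final <- vapply(hors$id, function(id) sum(sv == id),
                                  integer(1), USE.NAMES = FALSE)
    hors <- classify_hor_frequency(hors, dec, params)
  } else {
    hors$n_blocks_final <- integer(0)
    hors$freq_class <- character(0)
  }
  structure(list(hors = hors, decomposition = dec,
                 initial_alphabet = init_alpha, forbidden = forbidden,
                 log = if (length(log)) bind_rows(log) else tibble(),
                 input = s0, params = params),
            class = "hor_decomposition")
}

#' @export
print.hor_decomposition <- function(x, ...) {
  cat("<hor_decomposition> ", nrow(x$hors), " HORs; |S*| = ",
      length(x$decomposition), " (input ", length(x$input), " symbols)\n",
      sep = "")
  if (nrow(x$hors)) {
    df <- x$hors
    df$expansion <- vapply(df$expansion, paste, character(1), collapse = "")
    print(as_tibble(df))
  }
  cat("decomposition: ", format_symbol_string(x$decomposition), "\n", sep = "")
  invisible(x)
}

#' Assign HOR frequency classes
#'
#' A HOR is frequent when its count exceeds `|HORDecomposition| /
#' hor_freq_ceiling` where `|HORDecomposition|` is the number of elements of
#' the run-length-encoded decomposition; an infrequent HOR is rare when its
#' count does not exceed `rare_hor_count`.
#'
#' @param hors HOR definition tibble with a `count` column.
#' @param decomposition The run-length `symbol_string` (or an object whose
#'   `length()` is the element count).
#' @param params A [hor_params()] object.
#' @return `hors` with a `freq_class` column.
#' @export
classify_hor_frequency <- function(hors, decomposition, params = hor_params()) {
  denom <- length(decomposition)
  thr <- denom / params$hor_freq_ceiling
  hors$freq_class <- dplyr::case_when(
    hors$count > thr ~ "frequent",
    hors$count <= params$rare_hor_count ~ "rare",
    TRUE ~ "infrequent"
  )
  hors
}

#' Infer superHORs from a HOR decomposition
#'
#' Ignores all degrees in the HOR decomposition (each X^n becomes a single
#' X) and reruns the greedy substitution with the superHOR thresholds
#' (`super_min_count`, `super_min_weight`, inclusive comparisons) and no
#' monomer-containment requirement. Degrees are not re-attached; the
#' superHOR string is reported alongside the degree-bearing HOR string.
#'
#' @param hor_decomposition A `hor_decomposition` object, `symbol_string`,
#'   or flat symbol vector.
#' @param params A [hor_params()] object.
#' @return An object of class `super_hor_decomposition`: list with `hors`
#'   (superHOR definitions, `is_super = TRUE`), `decomposition` (the
#'   substituted degree-free `symbol_string`) and `input` (the
#'   degree-stripped string).
#' @export
super_hor_decompose <- function(hor_decomposition, params = hor_params()) {
  x <- hor_decomposition
  if (inherits(x, "hor_decomposition")) {
    stripped <- x$decomposition$symbols
    forbidden <- x$forbidden
    taken <- unique(c(x$input, x$hors$id))
  } else {
    stripped <- run_length_encode(.as_symbols(x))$symbols
    forbidden <- NONMONOMERIC_TOKEN
    taken <- unique(stripped)
  }
  sv <- stripped
  supers <- list()
  log <- list()
  k <- 0L
  repeat {
    sel <- select_hor(sv, params, initial_alphabet = NULL, inclusive = TRUE,
                      min_count = params$super_min_count,
                      min_weight = params$super_min_weight,
                      forbidden = forbidden)
    if (is.null(sel)) break
    k <- k + 1L
    id <- .fresh_hor_id("s", k, taken)
    taken <- c(taken, id)
    rb <- rle_len(sv)
    out <- substitute_symbols(sv, sel$h, id)
    log[[length(log) + 1L]] <- tibble(
      id = id, n_before = length(sv), rle_before = rb, count = sel$count,
      h_len = length(sel$h), n_after = length(out),
      rle_after = rle_len(out), weight = sel$weight)
    sv <- out
    supers[[length(supers) + 1L]] <- tibble(
      id = id, expansion = list(sel$h), n_monomers = NA_integer_,
      count = sel$count, weight = sel$weight, is_super = TRUE,
      is_canonical = FALSE)
  }
  supers <- if (length(supers)) bind_rows(supers) else
    tibble(id = character(0), expansion = list(), n_monomers = integer(0),
           count = integer(0), weight = integer(0), is_super = logical(0),
           is_canonical = logical(0))
  structure(list(hors = supers, decomposition = symbol_string(sv),
                 log = if (length(log)) bind_rows(log) else tibble(),
                 input = stripped),
            class = "super_hor_decomposition")
}

#' @export
print.super_hor_decomposition <- function(x, ...) {
  cat("<super_hor_decomposition> ", nrow(x$hors), " superHORs; length ",
      length(x$decomposition), " (input ", length(x$input), " symbols)\n",
      sep = "")
  cat("decomposition: ", format_symbol_string(x$decomposition), "\n", sep = "")
  invisible(x)
}

#' Expand a (super)HOR decomposition back to its flat symbol string
#'
#' Recursively replaces every degree-n element by n copies and every defined
#' HOR/superHOR symbol by its expansion until only base symbols remain.
#'
#' @param decomposition A `symbol_string` (or flat symbol vector).
#' @param defs HOR definition tibble (`id` + `expansion` list-column);
#'   definitions may reference each other.
#' @return Flat character vector of base symbols.
#' @export
expand_decomposition <- function(decomposition, defs) {
  flat <- ss_flat(decomposition)
  if (is.null(defs) || nrow(defs) == 0L) return(flat)
  ids <- defs$id
  for (depth in 1:100) {
    hit <- flat %in% ids
    if (!any(hit)) return(flat)
    flat <- unlist(lapply(flat, function(x) {
      if (x %in% ids) defs$expansion[[match(x, ids)]] else x
    }), use.names = FALSE)
  }
  abort("HOR definitions appear to be cyclic")
}
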