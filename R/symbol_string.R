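#' Symbol strings over a monomer/HOR alphabet
#'
#' A `symbol_string` is an ordered vector of symbols (monomer ids, HOR ids,
#' superHOR ids, or the non-monomeric `?` token) with a per-symbol degree for
#' its run-length form. Expanding every degree-n symbol to n copies (and,
#' given HOR definitions, every HOR symbol to its expansion) reconstructs the
#' underlying monostring exactly.
#'
#' @param symbols Character vector of symbols.
#' @param degrees Integer vector of run degrees (default all 1).
#' @return An object of class `symbol_string`.
#' @export
symbol_string <- function(symbols, degrees = rep(1L, length(symbols))) {
  stopifnot(is.character(symbols), length(degrees) == length(symbols),
            all(degrees >= 1L))
  structure(list(symbols = symbols, degrees = as.integer(degrees)),
            class = "symbol_string")
}

#' @export
length.symbol_string <- function(x) length(x$symbols)

#' @export
print.symbol_string <- function(x, ...) {
  cat("<symbol_string> ", length(x$symbols), " symbols\n", sep = "")
  cat(format_symbol_string(x), "\n")
  invisible(x)
}

#' @export
as.character.symbol_string <- function(x, ...) format_symbol_string(x)

# Flat symbol vector (degrees expanded).
ss_flat <- function(x) {
  if (inherits(x, "symbol_string")) rep(x$symbols, x$degrees)
  else if (inherits(x, "mono_string")) x$symbols
  else as.character(x)
}

rle_len <- function(symbols) {
  if (length(symbols) == 0L) return(0L)
  length(rle(symbols)$values)
}

#' Run-length encode a symbol string
#'
#' Collapses every maximal run of a symbol X of length n into a single
#' element X^n; each such element counts as one symbol, so
#' `length(run_length_encode(s))` is the run-length-encoded length |S*|.
#' Decoding with [run_length_decode()] inverts exactly.
#'
#' @param s A `symbol_string`, `mono_string`, or character vector of symbols.
#' @return A `symbol_string` in run-length form.
#' @examples
#' length(run_length_encode(strsplit("ABBCAAAD", "")[[1]]))  # 5
#' @export
run_length_encode <- function(s) {
  flat <- .as_symbols(s)
  if (length(flat) == 0L) return(symbol_string(character(0)))
  r <- rle(flat)
  symbol_string(r$values, r$lengths)
}

#' Expand a run-length symbol string back to flat form
#'
#' @param s A `symbol_string`.
#' @return A `symbol_string` with all degrees equal to 1.
#' @export
run_length_decode <- function(s) {
  symbol_string(ss_flat(s))
}

# ---- fast single-character encoding for substring operations -------------

# Symbols are mapped to consecutive Unicode code points so that substring
# counting and substitution can use C-level fixed-string matching.
SYM_BASE <- 0x4E00L

sym_encode <- function(symbols, alphabet) {
  idx <- match(symbols, alphabet)
  if (anyNA(idx)) abort("symbol not in alphabet")
  intToUtf8(SYM_BASE + idx)
}

sym_decode <- function(str, alphabet) {
  if (nchar(str) == 0L) return(character(0))
  alphabet[utf8ToInt(str) - SYM_BASE]
}

# gregexpr with a fixed pattern scans left to right and resumes after each
# match: exactly the leftmost non-overlapping occurrence rule.
.leftmost_starts <- function(enc_s, enc_h) {
  if (nchar(enc_s) < nchar(enc_h) || nchar(enc_h) == 0L) return(integer(0))
  m <- gregexpr(enc_h, enc_s, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Count non-overlapping occurrences of a pattern
#'
#' Greedy left-to-right scan: an occurrence of `h` is accepted whenever it
#' starts at the current position and does not overlap the previously
#' accepted occurrence.
#'
#' @param s Symbol string (character vector, `symbol_string`, `mono_string`,
#'   or a plain string of single-character symbols).
#' @param h Non-empty pattern over the same alphabet.
#' @return A list with `count` and `starts` (0-based start positions).
#' @examples
#' count_nonoverlapping("AABBCAAAD", "AA")  # count 2, starts 0 and 5
#' @export
count_nonoverlapping <- function(s, h) {
  sv <- .as_symbols(s); hv <- .as_symbols(h)
  if (length(hv) == 0L) abort("empty pattern")
  alpha <- unique(c(sv, hv))
  starts <- .leftmost_starts(sym_encode(sv, alpha), sym_encode(hv, alpha))
  list(count = length(starts), starts = starts - 1L)
}

# Plain strings of single-character symbols are a convenient input dialect
# for worked examples.
.as_symbols <- function(x) {
  if (inherits(x, c("symbol_string", "mono_string"))) return(ss_flat(x))
  stopifnot(is.character(x))
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1L]]
  else x
}

#' Substitute non-overlapping occurrences of a pattern by a new symbol
#'
#' Replaces every leftmost non-overlapping occurrence of `h` in `s` by the
#' single symbol `symbol`. The resulting length satisfies
#' `|S(h)| = |S| - count * (|h| - 1)`, and replacing `symbol` back by `h`
#' recovers `s` exactly.
#'
#' @inheritParams count_nonoverlapping
#' @param symbol New symbol id (must not occur in `s` or `h`).
#' @return Character vector of symbols after substitution.
#' @export
substitute_symbols <- function(s, h, symbol) {
  sv <- .as_symbols(s); hv <- .as_symbols(h)
  stopifnot(length(symbol) == 1L)
  if (symbol %in% c(sv, hv)) abort("replacement symbol already in alphabet")
  cs <- count_nonoverlapping(sv, hv)
  if (cs$count == 0L) return(sv)
  k <- length(hv)
  out <- character(0)
  prev <- 1L
  for (st in cs$starts + 1L) {
    if (st > prev) out <- c(out, sv[prev:(st - 1L)])
    out <- c(out, symbol)
    prev <- st + k
  }
  if (prev <= length(sv)) out <- c(out, sv[prev:length(sv)])
  out
}

#' Weight of a substring under the run-length objective
#'
#' `weight(S, h) = |S*| - |S(h)*|`: how much the run-length-encoded length of
#' S shrinks when every leftmost non-overlapping occurrence of h is replaced
#' by one new symbol.
#'
#' @inheritParams count_nonoverlapping
#' @return Integer weight (0 when `h` does not occur in `s`).
#' @export
hor_weight <- function(s, h) {
  sv <- .as_symbols(s)
  sub <- substitute_symbols(sv, h, "")
  rle_len(sv) - rle_len(sub)
}

#' Number of member strings forming a word
#'
#' A `Strings`-word is a concatenation of members of a string-set; its orbit
#' is the number of member strings used. If the forming sequence (`parse`) is
#' not supplied, a minimum-piece segmentation is derived by dynamic
#' programming; a word that cannot be formed from the set is an error.
#'
#' @param w The word (plain string or character vector of symbols).
#' @param strings Character vector: the string-set.
#' @param parse Optional explicit forming sequence of member strings.
#' @return Integer orbit.
#' @examples
#' orbit("ABBDCDAB", c("AB", "CD", "BD"))  # 4
#' @export
orbit <- function(w, strings, parse = NULL) {
  wv <- if (is.character(w) && length(w) == 1L) w else paste(.as_symbols(w), collapse = "")
  if (!is.null(parse)) {
    if (!all(parse %in% strings) || paste(parse, collapse = "") != wv) {
      abort("parse is not a forming sequence of w over strings")
    }
    return(length(parse))
  }
  n <- nchar(wv)
  if (n == 0L) return(0L)
  if (length(strings) == 0L) abort("w is not a word over an empty string-set")
  dp <- rep(NA_integer_, n + 1L)
  dp[1L] <- 0L
  slen <- nchar(strings)
  for (i in seq_len(n)) {
    for (k in seq_along(strings)) {
      L <- slen[k]
      if (L <= i && !is.na(dp[i - L + 1L]) &&
          substr(wv, i - L + 1L, i) == strings[k]) {
        cand <- dp[i - L + 1L] + 1L
        if (is.na(dp[i + 1L]) || cand < dp[i + 1L]) dp[i + 1L] <- cand
      }
    }
  }
  if (is.na(dp[n + 1L])) abort("w cannot be formed from the string-set")
  dp[n + 1L]
}

#' Score of a string-set decomposition
#'
#' `score(Strings, w) = orbit(w) + length(Strings)`, where `length(Strings)`
#' is the total length of the strings in the set.
#'
#' @inheritParams orbit
#' @return Integer score.
#' @export
decomposition_score <- function(strings, w, parse = NULL) {
  wv <- if (is.character(w) && length(w) == 1L) w else paste(.as_symbols(w), collapse = "")
  if (nchar(wv) == 0L && length(strings) == 0L) return(0L)
  orbit(wv, strings, parse) + sum(nchar(strings))
}
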