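# Deterministic evenly spaced subset (bounds consensus cost).
evenly_spaced <- function(x, max_n = 100L) {
  if (length(x) <= max_n) return(x)
  x[unique(round(seq(1L, length(x), length.out = max_n)))]
}

#' Iteratively infer a monomer set that resolves an array
#'
#' Starting from a single initial consensus monomer, repeatedly: decompose
#' the array into blocks; stop when the resolved fraction exceeds
#' `fraction_resolved_blocks` and every remaining block is non-monomeric;
#' otherwise build the block-graph of unresolved blocks (edges below half the
#' resolved-divergence threshold), add the consensus of its largest connected
#' component as a new monomer, drop monomers that are no block's most similar
#' monomer, and recompute every monomer as the consensus of its resolved
#' blocks. After termination the set is refined to a fixed point where each
#' monomer equals the consensus of the blocks it resolves.
#'
#' @param sequence The array nucleotide string.
#' @param initial_monomer A single starting consensus monomer; its length
#'   must lie within `length +/- max_length_divergence` of the parameters.
#' @param params A [monomer_gen_params()] object.
#' @param seq_id Sequence identifier for the block table.
#' @return An object of class `monomer_inference`: a list with `monomers`
#'   (statistics tibble, see [monomer_stats()]), `blocks` (final block
#'   tibble), `log` (per-iteration table: resolved/unresolved/non-monomeric
#'   counts, largest component, radius, separation to previously generated
#'   monomers, new monomer length) and `converged`.
#' @export
generate_monomers <- function(sequence, initial_monomer,
                              params = monomer_gen_params(), seq_id = NULL) {
  stopifnot(is.character(initial_monomer), length(initial_monomer) == 1L)
  initial_monomer <- toupper(unname(initial_monomer))
  if (abs(nchar(initial_monomer) - params$length) > params$max_length_divergence) {
    abort("initial monomer length outside length +/- max_length_divergence")
  }
  monomers <- tibble(id = "m001", seq = initial_monomer, is_nonmonomeric = FALSE)
  next_idx <- 2L
  log <- list()
  blocks <- NULL
  converged <- FALSE
  iter_done <- 0L

  for (iter in 0:(params$max_iterations - 1L)) {
    blocks <- decompose(sequence, monomers, params, seq_id = seq_id)
    n_res <- sum(blocks$status == "resolved")
    n_unres <- sum(blocks$status == "unresolved")
    n_nm <- sum(blocks$status == "non_monomeric")
    frac <- n_res / nrow(blocks)
    if (frac > params$fraction_resolved_blocks && n_unres == 0L) {
      log[[length(log) + 1L]] <- tibble(
        iter = iter, n_resolved = n_res, n_unresolved = n_unres,
        n_non_monomeric = n_nm, largest_component = NA_integer_,
        radius = NA_integer_, separation_prev = NA_integer_,
        monomer_length = NA_integer_)
      converged <- TRUE; iter_done <- iter
      break
    }
    unres <- blocks[blocks$status == "unresolved", ]
    bg <- build_block_graph(unres, params$max_resolved_divergence / 2)
    if (bg$n == 0L) {
      # nothing left to cluster but predicate unmet: stalled
      converged <- FALSE; iter_done <- iter
      break
    }
    comp_sizes <- bg$sizes
    biggest <- max(comp_sizes)
    cands <- which(comp_sizes == biggest)
    if (length(cands) > 1L) {  # tie: smallest minimum block start
      min_start <- vapply(cands, function(cc) {
        min(unres$start[bg$membership == cc])
      }, integer(1))
      cands <- cands[order(min_start)]
    }
    comp <- cands[1L]
    member_blocks <- unres[bg$membership == comp, ]
    member_blocks <- member_blocks[order(member_blocks$start), ]
    cons <- consensus(evenly_spaced(member_blocks$seq, 100L))$consensus
    new_id <- paste0("m", sprintf("%03d", next_idx)); next_idx <- next_idx + 1L
    radius_new <- max(edit_distance(rep(cons, nrow(member_blocks)),
                                    member_blocks$seq))
    sep_prev <- min(edit_matrix(cons, monomers$seq))
    log[[length(log) + 1L]] <- tibble(
      iter = iter, n_resolved = n_res, n_unresolved = n_unres,
      n_non_monomeric = n_nm, largest_component = biggest,
      radius = as.integer(radius_new), separation_prev = as.integer(sep_prev),
      monomer_length = nchar(cons))
    if (frac > params$fraction_resolved_blocks && biggest <= 1L) {
      # resolved fraction reached but residual unresolved blocks are isolated
      # singletons: adding them would only memorize single blocks
      converged <- TRUE; iter_done <- iter
      break
    }
    # removal of monomers that are no block's most similar monomer
    used <- unique(sub("'$", "", blocks$best_monomer))
    monomers <- monomers[monomers$id %in% used, , drop = FALSE]
    # recompute each monomer as the consensus of its resolved blocks
    monomers$seq <- vapply(seq_len(nrow(monomers)), function(i) {
      rb <- blocks$seq[blocks$best_monomer == monomers$id[i] &
                         blocks$status == "resolved"]
      if (length(rb) == 0L) monomers$seq[i]
      else consensus(evenly_spaced(rb, 100L))$consensus
    }, character(1))
    monomers <- bind_rows(monomers,
                          tibble(id = new_id, seq = cons, is_nonmonomeric = FALSE))
    iter_done <- iter
  }
  log <- bind_rows(log)
  if (!converged && iter_done >= params$max_iterations - 1L) {
    abort(paste0("monomer inference did not converge within ",
                 params$max_iterations, " iterations"),
          class = "horinfer_no_convergence", log = log)
  }

  # fixed-point refinement: each monomer must equal the consensus of the
  # blocks it resolves
  for (round in 1:5) {
    newseq <- vapply(seq_len(nrow(monomers)), function(i) {
      rb <- blocks$seq[blocks$best_monomer == monomers$id[i] &
                         blocks$status == "resolved"]
      if (length(rb) == 0L) monomers$seq[i]
      else consensus(evenly_spaced(rb, 100L))$consensus
    }, character(1))
    if (identical(newseq, monomers$seq)) break
    monomers$seq <- newseq
    blocks <- decompose(sequence, monomers, params, seq_id = seq_id)
  }
  used <- unique(sub("'$", "", blocks$best_monomer))
  monomers <- monomers[monomers$id %in% used, , drop = FALSE]

  stats <- monomer_stats(monomers, blocks, params)
  structure(list(monomers = stats, blocks = blocks, log = log,
                 params = params, converged = converged,
                 iterations = iter_done + 1L),
            class = "monomer_inference")
}

#' @export
print.monomer_inference <- function(x, ...) {
  cat("<monomer_inference> ", nrow(x$monomers), " monomers after ",
      x$iterations, " iterations (",
      sum(x$monomers$freq_class == "frequent"), " frequent)\n", sep = "")
  cat(sprintf("blocks: %d resolved / %d unresolved / %d non-monomeric\n",
              sum(x$blocks$status == "resolved"),
              sum(x$blocks$status == "unresolved"),
              sum(x$blocks$status == "non_monomeric")))
  invisible(x)
}

#' Monomer statistics and frequency classes
#'
#' For every monomer: its count (number of blocks whose most similar monomer
#' it is, non-monomeric blocks excluded), radius (maximum edit distance from
#' the monomer to those blocks), separation (minimum edit distance to any
#' other monomer), separation ratio (separation/radius, `Inf` when radius is
#' 0) and frequency class: `frequent` when the count exceeds
#' `n_blocks / freq_ceiling`, otherwise `infrequent`, and `rare` when the
#' count additionally does not exceed `rare_monomer_count`.
#'
#' @param monomers Monomer set (see [as_monomer_tbl()]).
#' @param blocks Block tibble from [decompose()] against that set.
#' @param params A [monomer_gen_params()] object.
#' @return The monomer tibble with `count`, `freq_class`, `radius`,
#'   `separation`, `separation_ratio` and `length_uniform` columns.
#' @export
monomer_stats <- function(monomers, blocks, params = monomer_gen_params()) {
  mon <- as_monomer_tbl(monomers)
  total <- nrow(blocks)
  core <- blocks[blocks$status != "non_monomeric", ]
  mon$count <- vapply(mon$id, function(id) {
    sum(sub("'$", "", core$best_monomer) == id)
  }, integer(1), USE.NAMES = FALSE)
  mon$radius <- vapply(seq_len(nrow(mon)), function(i) {
    bs <- core$seq[sub("'$", "", core$best_monomer) == mon$id[i]]
    if (length(bs) == 0L) return(NA_integer_)
    max(edit_distance(rep(mon$seq[i], length(bs)), bs))
  }, integer(1))
  if (nrow(mon) > 1L) {
    dm <- edit_matrix(mon$seq, mon$seq)
    diag(dm) <- NA_integer_
    mon$separation <- as.integer(apply(dm, 1L, min, na.rm = TRUE))
  } else {
    mon$separation <- NA_integer_
  }
  mon$separation_ratio <- ifelse(
    is.na(mon$radius) | is.na(mon$separation), NA_real_,
    ifelse(mon$radius == 0L, Inf, mon$separation / mon$radius))
  freq_threshold <- total / params$freq_ceiling
  mon$freq_class <- dplyr::case_when(
    mon$count > freq_threshold ~ "frequent",
    mon$count <= params$rare_monomer_count ~ "rare",
    TRUE ~ "infrequent"
  )
  mon$length_uniform <-
    abs(nchar(mon$seq) - params$length) <= params$max_length_divergence
  mon
}

#' Detect hybrid monomers
#'
#' For each candidate (infrequent) monomer M, searches over ordered pairs of
#' distinct frequent parent monomers (X, Y) and cut points (i, j) for the
#' concatenation of the i-prefix of X with the j-suffix of Y minimizing the
#' divergence to M. M is annotated as a hybrid X(i)+Y(j) when that divergence
#' does not exceed `max_hybrid_divergence`. By default the search is bounded
#' to candidates within 10% of `expected_length` and cut pairs with
#' `|i + j - |M|| <= 10`; `exhaustive = TRUE` removes both bounds.
#'
#' @param candidates Candidate monomers (see [as_monomer_tbl()]).
#' @param parents Frequent parent monomers.
#' @param max_hybrid_divergence Annotation threshold (fraction). Default 0.01.
#' @param expected_length Expected monomer length for the candidate-length
#'   bound; `NULL` disables that bound.
#' @param exhaustive Search all cut pairs and candidates.
#' @return A tibble with one row per candidate: `id`, `parent_x`,
#'   `prefix_len`, `parent_y`, `suffix_len`, `hybrid_divergence`,
#'   `is_hybrid`.
#' @export
detect_hybrids <- function(candidates, parents, max_hybrid_divergence = 0.01,
                           expected_length = NULL, exhaustive = FALSE) {
  cand <- as_monomer_tbl(candidates)
  par <- as_monomer_tbl(parents)
  if (nrow(par) == 0L) abort("parent monomer set is empty")
  par <- par[order(par$id, method = "radix"), ]
  window <- if (exhaustive) -1L else 10L
  rows <- purrr::map(seq_len(nrow(cand)), function(ci) {
    m <- cand$seq[ci]
    out <- tibble(id = cand$id[ci], parent_x = NA_character_,
                  prefix_len = NA_integer_, parent_y = NA_character_,
                  suffix_len = NA_integer_, hybrid_divergence = NA_real_,
                  is_hybrid = FALSE)
    if (!exhaustive && !is.null(expected_length) &&
        abs(nchar(m) - expected_length) > 0.1 * expected_length) {
      return(out)
    }
    best <- NULL
    for (xi in seq_len(nrow(par))) {
      for (yi in seq_len(nrow(par))) {
        if (xi == yi) next
        h <- cpp_hybrid_best(m, par$seq[xi], par$seq[yi], window)
        if (is.na(h[["dist"]])) next
        div <- h[["dist"]] / max(nchar(m), h[["i"]] + h[["j"]])
        if (is.null(best) || div < best$div) {
          best <- list(div = div, x = par$id[xi], i = h[["i"]],
                       y = par$id[yi], j = h[["j"]])
        }
      }
    }
    if (!is.null(best)) {
      out$parent_x <- best$x; out$prefix_len <- as.integer(best$i)
      out$parent_y <- best$y; out$suffix_len <- as.integer(best$j)
      out$hybrid_divergence <- best$div
      out$is_hybrid <- best$div <= max_hybrid_divergence
    }
    out
  })
  bind_rows(rows)
}
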