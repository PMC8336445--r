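#' Specification for a synthetic nested tandem repeat
#'
#' Describes a simulated satellite array: a monomer alphabet generated by
#' mutating a common random ancestor (so that pairwise monomer divergences
#' fall within 20% of the requested value, as for real alpha-satellite
#' monomer families), a HOR unit given as a pattern of monomer indices,
#' tandemly repeated with per-copy mutations, optional variant units and
#' optional non-monomeric insertions.
#'
#' @param n_monomers Number of distinct monomers in the alphabet.
#' @param monomer_length Monomer length in bp (default 171, the human
#'   alpha-satellite unit length).
#' @param inter_monomer_divergence Target pairwise divergence between
#'   monomers (default 0.25, matching the 65--88% identities of human
#'   alpha-satellite monomers).
#' @param hor_pattern Integer vector of monomer indices forming one HOR unit
#'   (repeats allowed); default one copy of each monomer.
#' @param n_units Number of tandem HOR units (default 100).
#' @param mutation_rate Per-bp mutation rate applied independently to every
#'   monomer copy (default 0.01; HOR copies in real centromeres are 95-100%
#'   identical).
#' @param indel_fraction Fraction of mutations that are indels rather than
#'   substitutions (default 0.1); indel lengths are capped at 3 bp.
#' @param variant_units List of `list(pattern =, freq =)` entries: alternate
#'   unit patterns planted at the given frequency.
#' @param insertions List of `list(length =, after_unit =)` entries:
#'   non-monomeric random segments planted between units.
#' @param seed Integer seed; the simulation is a pure function of the spec.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_monomers, monomer_length = 171L,
                            inter_monomer_divergence = 0.25,
                            hor_pattern = seq_len(n_monomers),
                            n_units = 100L, mutation_rate = 0.01,
                            indel_fraction = 0.1,
                            variant_units = list(), insertions = list(),
                            seed = 1L) {
  stopifnot(n_monomers >= 1L, monomer_length >= 10L,
            inter_monomer_divergence >= 0, inter_monomer_divergence < 1,
            length(hor_pattern) >= 1L,
            all(hor_pattern %in% seq_len(n_monomers)),
            n_units >= 1L, mutation_rate >= 0, mutation_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  for (v in variant_units) {
    stopifnot(all(v$pattern %in% seq_len(n_monomers)),
              v$freq >= 0, v$freq <= 1)
  }
  for (ins in insertions) {
    stopifnot(ins$length >= 1L, ins$after_unit >= 0L, ins$after_unit <= n_units)
  }
  structure(list(n_monomers = n_monomers, monomer_length = monomer_length,
                 inter_monomer_divergence = inter_monomer_divergence,
                 hor_pattern = as.integer(hor_pattern),
                 n_units = as.integer(n_units),
                 mutation_rate = mutation_rate,
                 indel_fraction = indel_fraction,
                 variant_units = variant_units, insertions = insertions,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

.random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# Fixed number of substitutions at distinct positions (low-variance monomer
# alphabet generation).
.mutate_fixed_subs <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), min(n_sub, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# Per-bp substitutions plus short (<= 3 bp) indels.
.mutate_copy <- function(seq, rate, indel_fraction) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  sub_idx <- which(stats::runif(L) < rate * (1 - indel_fraction))
  for (p in sub_idx) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  n_indel <- stats::rbinom(1L, L, rate * indel_fraction)
  if (n_indel > 0L) {
    for (k in seq_len(n_indel)) {
      len <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
      if (stats::runif(1) < 0.5 && length(ch) > len) {           # deletion
        p <- sample(length(ch) - len + 1L, 1L)
        ch <- ch[-(p:(p + len - 1L))]
      } else {                                                    # insertion
        p <- sample(length(ch) + 1L, 1L)
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        ch <- append(ch, ins, after = p - 1L)
      }
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a nested tandem repeat with ground truth
#'
#' Deterministic for a fixed spec (the seed covers every random draw).
#' Monomers are generated by mutating a random ancestor and rejected /
#' regenerated until all pairwise divergences lie within 20% of the target.
#'
#' @param spec A [simulation_spec()].
#' @param max_tries Resampling budget for the divergence constraint.
#' @return A list of class `simulated_array`: `sequence` (named nucleotide
#'   string), `monomers` (tibble `id`, `seq`: the planted alphabet),
#'   `truth` (tibble `seq_id`, `start`, `end`, `monomer`, `unit`, `type`
#'   tiling the sequence; insertions have `type = "insertion"`) and `spec`.
#' @export
simulate_array <- function(spec, max_tries = 200L) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$monomer_length
    d <- spec$inter_monomer_divergence
    ancestor <- .random_seq(L)
    n_sub <- round(d / 2 * L)
    monos <- vapply(seq_len(spec$n_monomers), function(i) {
      .mutate_fixed_subs(ancestor, n_sub)
    }, character(1))
    if (spec$n_monomers > 1L && d > 0) {
      lo <- 0.8 * d; hi <- 1.2 * d
      for (try in seq_len(max_tries)) {
        dm <- edit_matrix(monos, monos) / L
        diag(dm) <- NA_real_
        bad <- dm < lo | dm > hi
        viol <- rowSums(bad, na.rm = TRUE)
        if (all(viol == 0L)) break
        worst <- which.max(viol)
        monos[worst] <- .mutate_fixed_subs(ancestor, n_sub)
        if (try == max_tries) {
          abort("could not satisfy the inter-monomer divergence constraint")
        }
      }
    }
    mon_ids <- paste0("T", sprintf("%02d", seq_len(spec$n_monomers)))

    # assign variant patterns to units
    unit_pattern <- rep(list(spec$hor_pattern), spec$n_units)
    available <- seq_len(spec$n_units)
    for (v in spec$variant_units) {
      n_var <- round(v$freq * spec$n_units)
      if (n_var == 0L || length(available) == 0L) next
      pick <- sort(sample(available, min(n_var, length(available))))
      for (u in pick) unit_pattern[[u]] <- as.integer(v$pattern)
      available <- setdiff(available, pick)
    }
    ins_after <- vapply(spec$insertions, function(x) as.integer(x$after_unit),
                        integer(1))

    pieces <- character(0)
    truth <- list()
    pos <- 0L
    add_piece <- function(s, monomer, unit, type) {
      pieces[[length(pieces) + 1L]] <<- s
      truth[[length(truth) + 1L]] <<- tibble(
        start = pos, end = pos + nchar(s), monomer = monomer,
        unit = unit, type = type)
      pos <<- pos + nchar(s)
    }
    emit_insertions <- function(after) {
      for (k in which(ins_after == after)) {
        add_piece(.random_seq(spec$insertions[[k]]$length),
                  NA_character_, NA_integer_, "insertion")
      }
    }
    emit_insertions(0L)
    for (u in seq_len(spec$n_units)) {
      for (mi in unit_pattern[[u]]) {
        add_piece(.mutate_copy(monos[mi], spec$mutation_rate,
                               spec$indel_fraction),
                  mon_ids[mi], u, "monomer")
      }
      emit_insertions(u)
    }
    sequence <- paste(pieces, collapse = "")
    names(sequence) <- "sim1"
    truth <- bind_rows(truth)
    truth <- dplyr::bind_cols(tibble(seq_id = rep("sim1", nrow(truth))), truth)
    structure(list(sequence = sequence,
                   monomers = tibble(id = mon_ids, seq = unname(monos)),
                   truth = truth, spec = spec),
              class = "simulated_array")
  })
}

#' @export
print.simulated_array <- function(x, ...) {
  cat("<simulated_array> ", nchar(x$sequence), " bp, ",
      nrow(x$monomers), " monomers, ",
      sum(x$truth$type == "monomer"), " monomer blocks, ",
      sum(x$truth$type == "insertion"), " insertions\n", sep = "")
  invisible(x)
}

#' Compare predicted annotation against simulated ground truth
#'
#' Blocks are matched to truth intervals by at least 50% reciprocal overlap.
#' If predicted and true monomer sets are supplied they are matched by
#' greedy minimum-divergence bipartite matching.
#'
#' @param predicted Predicted block tibble (`start`, `end`; 0-based
#'   half-open).
#' @param truth Truth tibble from [simulate_array()] (rows with
#'   `type == "insertion"` are excluded from block matching).
#' @param monomers_pred,monomers_true Optional monomer sets
#'   (see [as_monomer_tbl()]) for divergence matching.
#' @return A list of class `truth_comparison`: `precision`, `recall`,
#'   `phase_shift` flag, `matches` (pred/truth index pairs with start
#'   offsets) and `monomer_matches` (tibble with matched divergences, or
#'   `NULL`).
#' @export
truth_compare <- function(predicted, truth,
                          monomers_pred = NULL, monomers_true = NULL) {
  tr <- truth[truth$type != "insertion", , drop = FALSE]
  np <- nrow(predicted); nt <- nrow(tr)
  if (np == 0L || nt == 0L) {
    res <- list(precision = if (np == 0L) NA_real_ else 0,
                recall = 0, phase_shift = FALSE,
                matches = tibble(pred = integer(0), truth = integer(0),
                                 offset = integer(0)),
                monomer_matches = NULL)
    return(structure(res, class = "truth_comparison"))
  }
  pr <- IRanges::IRanges(start = predicted$start + 1L, end = predicted$end)
  trr <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
  ov <- IRanges::findOverlaps(pr, trr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(pr[qh], trr[sh]))
  ok <- w >= 0.5 * IRanges::width(pr[qh]) & w >= 0.5 * IRanges::width(trr[sh])
  matches <- tibble(pred = qh[ok], truth = sh[ok],
                    offset = predicted$start[qh[ok]] - tr$start[sh[ok]])
  precision <- length(unique(matches$pred)) / np
  recall <- length(unique(matches$truth)) / nt
  phase_shift <- nrow(matches) > 0L &&
    median(abs(matches$offset)) > 0.05 * median(IRanges::width(trr))
  mm <- NULL
  if (!is.null(monomers_pred) && !is.null(monomers_true)) {
    mp <- as_monomer_tbl(monomers_pred); mt <- as_monomer_tbl(monomers_true)
    dm <- edit_matrix(mt$seq, mp$seq) / outer(nchar(mt$seq), nchar(mp$seq), pmax)
    dimnames(dm) <- list(mt$id, mp$id)
    rows <- list()
    while (nrow(dm) > 0 && ncol(dm) > 0) {
      ij <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
      rows[[length(rows) + 1L]] <- tibble(
        true_id = rownames(dm)[ij[1L]],
        pred_id = colnames(dm)[ij[2L]],
        divergence = dm[ij[1L], ij[2L]])
      dm <- dm[-ij[1L], -ij[2L], drop = FALSE]
    }
    mm <- bind_rows(rows)
  }
  structure(list(precision = precision, recall = recall,
                 phase_shift = phase_shift, matches = matches,
                 monomer_matches = mm),
            class = "truth_comparison")
}

#' @export
print.truth_comparison <- function(x, ...) {
  cat(sprintf("<truth_comparison> precision %.3f, recall %.3f%s\n",
              x$precision, x$recall,
              if (isTRUE(x$phase_shift)) " (phase-shifted)" else ""))
  if (!is.null(x$monomer_matches)) {
    cat("matched monomer divergences: ",
        paste(sprintf("%.3f", x$monomer_matches$divergence), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
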