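#' Parameters for array-to-block decomposition
#'
#' Thresholds governing how a satellite array is partitioned into monomeric
#' blocks and how each block is classified. A block is `resolved` when its
#' divergence to the most similar monomer is below `max_resolved_divergence`,
#' `non_monomeric` when it exceeds `max_divergence`, and `unresolved`
#' otherwise.
#'
#' @param max_resolved_divergence Fraction in (0, 1); blocks below this
#'   divergence from their best monomer are resolved. Default 0.05.
#' @param max_divergence Fraction in (0, 1]; blocks above this divergence from
#'   every monomer are non-monomeric. Default 0.40.
#' @param allow_reverse If `TRUE`, reverse complements of the monomers are
#'   added as additional alignment candidates. Default `FALSE`.
#' @return A list of class `decomposition_params`.
#' @export
decomposition_params <- function(max_resolved_divergence = 0.05,
                                 max_divergence = 0.40,
                                 allow_reverse = FALSE) {
  stopifnot(is.numeric(max_resolved_divergence), is.numeric(max_divergence))
  if (!(max_resolved_divergence > 0 && max_resolved_divergence < max_divergence &&
        max_divergence <= 1)) {
    abort("need 0 < max_resolved_divergence < max_divergence <= 1")
  }
  structure(
    list(max_resolved_divergence = max_resolved_divergence,
         max_divergence = max_divergence,
         allow_reverse = isTRUE(allow_reverse)),
    class = "decomposition_params"
  )
}

#' Parameters for iterative monomer inference
#'
#' Defaults follow the standard alpha-satellite setting: monomers of expected
#' length 171 bp, a 5% resolved-divergence threshold, and an array considered
#' resolved when more than 95% of blocks are resolved and the remainder are
#' non-monomeric.
#'
#' @inheritParams decomposition_params
#' @param fraction_resolved_blocks Stop once the resolved fraction exceeds
#'   this value (and all other blocks are non-monomeric). Default 0.95.
#' @param freq_ceiling A monomer is frequent when its count exceeds
#'   `n_blocks / freq_ceiling`. Default 40.
#' @param rare_monomer_count An infrequent monomer is rare when its count does
#'   not exceed this. Default 5.
#' @param max_hybrid_divergence Maximum divergence between an infrequent
#'   monomer and its best hybrid candidate for a hybrid call. Default 0.01.
#' @param length Expected monomer length in bp. Default 171.
#' @param max_length_divergence Length-uniformity band around `length`;
#'   default `0.01 * length`.
#' @param max_iterations Safety cap on monomer-inference iterations.
#' @return A list of class `monomer_gen_params`.
#' @export
monomer_gen_params <- function(max_resolved_divergence = 0.05,
                               max_divergence = 0.40,
                               fraction_resolved_blocks = 0.95,
                               freq_ceiling = 40,
                               rare_monomer_count = 5,
                               max_hybrid_divergence = 0.01,
                               length = 171,
                               max_length_divergence = 0.01 * length,
                               allow_reverse = FALSE,
                               max_iterations = 100) {
  stopifnot(fraction_resolved_blocks > 0, fraction_resolved_blocks <= 1,
            freq_ceiling >= 1, rare_monomer_count >= 1,
            max_hybrid_divergence > 0, length >= 1, max_iterations >= 1)
  p <- decomposition_params(max_resolved_divergence, max_divergence, allow_reverse)
  structure(
    c(unclass(p),
      list(fraction_resolved_blocks = fraction_resolved_blocks,
           freq_ceiling = freq_ceiling,
           rare_monomer_count = rare_monomer_count,
           max_hybrid_divergence = max_hybrid_divergence,
           length = length,
           max_length_divergence = max_length_divergence,
           max_iterations = max_iterations)),
    class = c("monomer_gen_params", "decomposition_params")
  )
}

#' Parameters for greedy HOR inference
#'
#' A candidate substring is recurrent when its non-overlapping occurrence
#' count passes `min_count`, short when no longer than `max_length` symbols,
#' and heavy when the run-length-encoding reduction it buys passes
#' `min_weight`. The main HOR pass uses strict (greater-than) comparisons;
#' the superHOR pass uses inclusive comparisons with `super_min_count` and
#' `super_min_weight` (see the methods vignette).
#'
#' @param min_count Occurrence threshold (strict) for HOR candidates. Default 5.
#' @param max_length Maximum candidate length in symbols. Default 30.
#' @param min_weight Weight threshold (strict) for HOR candidates. Default 5.
#' @param hor_freq_ceiling A HOR is frequent when its count exceeds
#'   `decomposition length / hor_freq_ceiling`. Default 40.
#' @param rare_hor_count An infrequent HOR is rare when its count does not
#'   exceed this. Default 10.
#' @param super_min_count Occurrence threshold (inclusive) for superHOR
#'   candidates. Default 2.
#' @param super_min_weight Weight threshold (inclusive) for superHOR
#'   candidates. Default 2.
#' @return A list of class `hor_params`.
#' @export
hor_params <- function(min_count = 5, max_length = 30, min_weight = 5,
                       hor_freq_ceiling = 40, rare_hor_count = 10,
                       super_min_count = 2, super_min_weight = 2) {
  stopifnot(min_count >= 0, max_length >= 2, min_weight >= 0,
            hor_freq_ceiling >= 1, rare_hor_count >= 1,
            super_min_count >= 1, super_min_weight >= 1)
  structure(
    list(min_count = min_count, max_length = max_length,
         min_weight = min_weight, hor_freq_ceiling = hor_freq_ceiling,
         rare_hor_count = rare_hor_count,
         super_min_count = super_min_count,
         super_min_weight = super_min_weight),
    class = "hor_params"
  )
}
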