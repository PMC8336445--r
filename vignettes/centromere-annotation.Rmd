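---
title: "Inferring monomers and higher-order repeats in satellite arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring monomers and higher-order repeats in satellite arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(horinfer)
```

## The annotation problem

Alpha-satellite arrays in live centromeres are nested tandem repeats:
~171 bp monomers, 65–88% identical to each other, are arranged into
higher-order repeat (HOR) units that recur hundreds to thousands of times at
95–100% identity, occasionally interrupted by retrotransposon insertions.
`horinfer` annotates such an array in two stages — infer the monomer
alphabet, then infer the HOR grammar over that alphabet — with every
concept given an explicit, testable definition.

Throughout, the *divergence* of two strings is their unit-cost edit
distance divided by the length of the longer string: symmetric, zero
exactly on equality, and at most 1.

## Block decomposition

`decompose()` partitions the array into consecutive blocks, each globally
aligned to one monomer, by a joint dynamic program over the sequence: entry
into a monomer is free at any position, alignment moves cost match +1 and
mismatch/indel −1, and exiting a monomer's last position at sequence
position *r* feeds the best prefix score at *r*. The scoring itself is a
local convention — any consistent scheme satisfying the tiling contract
would do — and the suite checks it against a brute-force tiling oracle on
instances up to 60 bp. Properties enforced on every run: blocks tile the
sequence exactly (no gaps, no overlaps), and terminal partial monomers are
ordinary short blocks classified by their divergence.

A block is **resolved** if its divergence to the most similar monomer is
below `max_resolved_divergence` (default 0.05), **non-monomeric** above
`max_divergence` (default 0.40), **unresolved** otherwise. Both thresholds
are strict; boundary values are unresolved. Ties for the most similar
monomer are broken by the lexicographically smallest monomer id so all
outputs are deterministic.

`augment_with_nonmonomeric()` extracts maximal runs of non-monomeric
blocks, clusters them by single linkage at `max_resolved_divergence`, and
adds each cluster consensus to the alphabet flagged non-monomeric, so an
Alu- or LINE-like insertion becomes a single named block rather than a
stretch of `?` symbols.

## Monomer inference

`generate_monomers()` starts from one initial consensus monomer (its length
must be within `length ± max_length_divergence`, defaults 171 ± 1.71) and
iterates: decompose; stop when the resolved fraction exceeds
`fraction_resolved_blocks` (0.95) *and* every remaining block is
non-monomeric; otherwise connect unresolved blocks whose divergence is
below `max_resolved_divergence / 2` in a block-graph, add the consensus of
its largest connected component as a new monomer (component-size ties break
to the smallest minimum block start), drop monomers that are no block's
most similar monomer, and recompute every monomer as the consensus of its
resolved blocks.

Design choices where the procedure was genuinely open:

* **Termination safeguard.** If the resolved fraction has passed its
  threshold but the remaining unresolved blocks are isolated singletons in
  the block-graph, the loop stops rather than memorising single blocks one
  iteration at a time. A hard `max_iterations` cap (default 100) turns
  non-convergence into an explicit error carrying the iteration table.
* **Fixed point.** After termination the set is refined (at most five
  rounds of consensus recomputation and re-decomposition) until each
  monomer equals the consensus of the blocks it resolves; on the clean
  fixtures used in the tests one round suffices.
* **Block-graph scaling.** All-pairs edit distance over unresolved blocks
  is quadratic, so candidate pairs are prefiltered by a q-gram count bound
  (strings within edit distance *e* share at least
  `(min_len − q + 1) − e·q` q-gram occurrences; the count-profile inner
  product upper-bounds the shared count, so the filter can only
  over-include) plus a length-difference bound, then verified with a banded
  edit distance. The brute-force graph is the oracle in the tests.
* **Consensus engine.** A deterministic center-star consensus: the center
  minimises total edit distance over a bounded, evenly spaced candidate
  subset; all strings are pairwise aligned to it; columns vote with the
  fixed nucleotide order A < C < G < T on ties, a gap losing ties to any
  nucleotide; insertions relative to the center are emitted when present in
  more than half of the inputs. Consensus inputs are capped at 100 evenly
  spaced blocks, which bounds the cost without materially moving a majority
  vote. Because blocks entering one consensus are within a few percent of
  each other, a progressive scheme would produce the same columns in
  practice.
* **Statistics.** A monomer's *count* and *radius* are taken over the
  blocks whose most similar monomer it is, excluding non-monomeric blocks
  (a single 500 bp insertion would otherwise dominate a radius); the
  frequency denominator `n_blocks / freq_ceiling` keeps all blocks.
  *Separation* is the smallest edit distance to any other monomer, and the
  separation ratio (separation/radius, `Inf` at radius 0) summarises how
  unambiguous block assignment is. The per-iteration log reports separation
  to the *previously generated* monomers, matching the convention of the
  iteration tables this log mirrors; `monomer_stats()` reports the
  all-monomers version.

**Hybrid monomers.** For an infrequent monomer *M*, `detect_hybrids()`
scans ordered pairs of distinct frequent parents (X, Y) and all cut points
for the concatenation of X's i-prefix with Y's j-suffix closest to *M*
(computed by the standard forward/backward DP join, so one (X, Y) pair
costs O(|X||M|) rather than one alignment per cut). *M* is annotated when
that divergence is at most `max_hybrid_divergence` (1%). The default search
is bounded — candidates within 10% of the expected length, cuts with
`|i + j − |M|| ≤ 10` — because an unbounded search adds cost without
plausible hybrids; `exhaustive = TRUE` removes both bounds and the tests
confirm the bounded search finds the planted optimum.

## Shifted monomer-sets

A tandem repeat's unit is defined only up to cyclic phase; in a *nested*
repeat, shifting all monomer starts by *i* nucleotides produces hybrids of
adjacent monomers, so the whole monostring is needed. `shift_monomers()`
derives one candidate per monomer-graph edge (the i-suffix of M joined to
the (|M′|−i)-prefix of M′), then merges candidates by single linkage at
divergence ≤ `merge_threshold` (half the resolved threshold, mirroring the
block-graph construction); the merged representative is the consensus of
member candidates weighted by source-edge weight, a choice the procedure
leaves open. Weight-1 edges are retained and reported. The shifted
monomer-graph connects the shifted monomers of overlapping edges once per
consecutive monomer triple.

## HOR inference

Definitions, all implemented literally: `orbit(w)` is the number of member
strings forming a word; `score(Strings, w) = orbit(w) + length(Strings)`;
run-length encoding `S*` counts each power `X^n` as one symbol;
`count_S(h)` takes leftmost non-overlapping occurrences (a greedy
left-to-right scan); the h-substitution replaces them by one new symbol, so
`|S(h)| = |S| − count·(|h|−1)`; `weight(S,h) = |S*| − |S(h)*|`. Each
substitution changes the score by exactly `−count·(|h|−1) + |h|`, an
identity the tests assert at every iteration, and the weight is strictly
positive for every accepted candidate, which is the termination argument.

`select_hor()` enumerates all substrings of 2..`max_length` symbols
(feasible because candidates are bounded at 30 symbols and counting uses
C-level fixed-string scans), filters to recurrent, heavy, non-trivial
candidates containing at least one original monomer symbol, and returns one
minimising `|S(h)*|`; ties break to the shortest candidate, then the
lexicographically smallest expansion. Candidates may contain previously
created HOR symbols (nested definitions) but never the non-monomeric token
or an alphabet string flagged non-monomeric — insertions therefore appear
inline in reports (`b_LINE_c`) but never inside a HOR.

Two documented threshold subtleties:

* The main pass uses strict comparisons (counts and weights must *exceed*
  their thresholds). The superHOR pass (`super_hor_decompose()`: strip all
  degrees, rerun with `MinCount = 2`, `MinWeight = 2`, no
  monomer-containment requirement) uses inclusive comparisons: the
  motivating example — the superHOR `bc` in `CbcbaBcbcDbD` — has count
  exactly 2 and weight exactly 2, so strict thresholds would reject the
  very pattern the relaxed parameters exist to find.
* The classic three-step demonstration chain (substitute `EGF`, then `AB`,
  then `Da` on `CABDEGFABEGFBDEGFABDEGFDABABDD`, ending at
  `CbcbaBcbcDb^2^D^2^`) is stated with thresholds under which none of those
  candidates is heavy, and under the min-`|S(h)*|` objective a different
  candidate (`DEGF`, `|S(h)*| = 20`) would in fact be selected first. No
  single consistent rule reproduces that selection order, so the package
  does not contort the selector; the chain is reproduced through the
  canonical-HOR seeding mechanism, which exists precisely to force given
  substitutions in a given order.

**Canonical seeding.** Known HORs supplied to `hor_decompose()` are
substituted first, in order, exempt from thresholds, and kept in the output
even at count 0 — consistency with previously published HOR nomenclature is
the purpose, so absence from a particular array is information, not an
error.

**Counting conventions.** A HOR's `count` is its substitution-time
occurrence count (equivalently its number of units after expanding
degrees, including occurrences later absorbed into nested HORs);
`n_blocks_final` counts its symbols in the final decomposition. Frequency
uses count against `|decomposition| / hor_freq_ceiling`, where
`|decomposition|` is the number of run-length elements; an infrequent HOR
with count ≤ `rare_hor_count` is rare. Degrees are not re-attached to the
superHOR string: split runs such as `ga^3^ga^15^ga^6^` only become the
compact `(ga)^n` because the degrees were dropped.

Losslessness is an invariant, not a hope: `expand_decomposition()`
recursively expands degrees and definitions, and the suite asserts on every
fixture that the expansion reproduces the input monostring byte for byte.

## The simulator

`simulate_array()` generates the study conditions the tests and the
acceptance suite run under: a monomer alphabet built by mutating a common
random ancestor (mirroring alpha-satellite descent, and giving realistic
65–88% identities at the default 0.25 target divergence) with exactly
`round(d/2 · L)` substitutions per monomer, rejection-resampling the worst
offender until all pairwise divergences sit within 20% of the target; HOR
units tandemly repeated (default 100 units) with per-bp mutations (default
0.01, of which 10% are indels capped at 3 bp, keeping length-uniformity
plausible); optional variant units and non-monomeric insertions; all
randomness under one seed, so identical specs give identical bytes.

What it does *not* emulate: assembly or sequencing error, divergent HOR
layers (old, highly diverged array margins), monomers shared across
chromosomes, and biased mutation spectra. Passing the recovery tests
therefore shows the algorithms invert the generative model they were
designed for — clean homogeneous arrays — not that every real centromere
resolves this cleanly.

Problem sizes used by the automated checks — k ∈ {2, 5, 12} planted
monomers at 1% per-copy mutation with 100 HOR units (up to ~205 kb of
sequence) — are the package's chosen validation scale; the recovery
criteria are exact (k frequent monomers, matched divergence ≤ the mutation
rate, planted unit recovered up to rotation, planted exact hybrids at
divergence 0).

## Numerical and degenerate-input choices

* Strict inequalities at every threshold boundary ("exceeds"/"below"),
  except the superHOR pass as discussed.
* Empty inputs: divergence of two empty strings, consensus of an empty
  list, and decomposition with an empty monomer set are errors; an empty
  block list yields an empty monostring; an empty word has orbit 0.
* `radius = 0` reports a separation ratio of `Inf`; a singleton monomer
  set has no separation.
* Coordinates are 0-based half-open internally and in TSV/BED output;
  divergences are printed as percentages with two decimals, which bounds
  TSV round-trip error at 5·10⁻⁵.
* Reverse-strand candidates are off by default (satellite arrays are
  conventionally annotated on one strand); `allow_reverse` adds reverse
  complements as extra candidates with ids marked by a trailing `'`.

## Known limitations

The greedy decomposer approximates the score-minimisation problem; it can
return different (equally valid) grammars under symbol relabelling, and
nothing guarantees global optimality. Monomer inference assumes a
high-quality assembly; read-level noise and diploid mixtures are out of
scope. Very diverged array layers that never form tight block-graph
components will stay unresolved and are reported as such rather than
forced into monomers.
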