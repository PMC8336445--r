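S_WALK <- "CABDEGFABEGFBDEGFABDEGFDABABDD"

test_that("orbit counts the member strings forming a word", {
  expect_identical(orbit("ABBDCDAB", c("AB", "CD", "BD")), 4L)
  expect_identical(orbit("", c("AB")), 0L)
  expect_identical(orbit("AB", c("AB", "CD")), 1L)
  expect_identical(orbit("ABBDCDAB", c("AB", "CD", "BD"),
                         parse = c("AB", "BD", "CD", "AB")), 4L)
  expect_error(orbit("ABC", c("AB", "CD")), "cannot be formed")
  expect_error(orbit("ABBD", c("AB", "CD"), parse = c("AB", "BD")),
               "not a forming sequence")
})

test_that("decomposition score is orbit plus total set length", {
  expect_identical(decomposition_score(c("AB", "CD", "BD"), "ABBDCDAB"), 10L)
  # alphabet-only decomposition of S scores |S| + |A|
  A <- c("A", "B", "C")
  S <- "ABCCBA"
  expect_identical(decomposition_score(A, S), nchar(S) + length(A))
  expect_identical(decomposition_score(character(0), ""), 0L)
})

test_that("run-length encoding collapses runs and counts powers once", {
  r <- run_length_encode("ABBCAAAD")
  expect_identical(length(r), 5L)
  expect_identical(r$symbols, c("A", "B", "C", "A", "D"))
  expect_identical(r$degrees, c(1L, 2L, 1L, 3L, 1L))
  expect_identical(length(run_length_encode("AAAA")), 1L)
  expect_identical(length(run_length_encode(character(0))), 0L)
})

test_that("run-length encode/decode round-trips random strings", {
  withr::with_seed(20, {
    for (k in 1:25) {
      s <- sample(LETTERS[1:4], sample(0:60, 1), replace = TRUE)
      rt <- horinfer:::ss_flat(run_length_decode(run_length_encode(s)))
      expect_identical(rt, s)
    }
  })
})

test_that("leftmost non-overlapping counting matches the worked examples", {
  cs <- count_nonoverlapping("AABBCAAAD", "AA")
  expect_identical(cs$count, 2L)
  expect_identical(cs$starts, c(0L, 5L))
  expect_identical(count_nonoverlapping("BBBB", "AA")$count, 0L)
  expect_identical(count_nonoverlapping(S_WALK, "AB")$count, 5L)
})

test_that("substitution reproduces the printed strings and length identity", {
  sh <- substitute_symbols(S_WALK, "AB", "h")
  expect_identical(paste(sh, collapse = ""), "ChDEGFhEGFBDEGFhDEGFDhhDD")
  expect_identical(length(sh), 25L)                       # |S| - 5*(2-1)
  expect_identical(horinfer:::rle_len(sh), 23L)
  sg <- substitute_symbols(S_WALK, "EGF", "g")
  expect_identical(paste(sg, collapse = ""), "CABDgABgBDgABDgDABABDD")
  expect_identical(length(sg), 22L)
  expect_identical(horinfer:::rle_len(sg), 21L)
  # absent pattern leaves the string unchanged
  expect_identical(substitute_symbols(S_WALK, "ZZ", "q"),
                   strsplit(S_WALK, "")[[1]])
  # substitution is invertible
  back <- expand_decomposition(
    symbol_string(sh), tibble::tibble(id = "h", expansion = list(c("A", "B")),
                                      count = 5L))
  expect_identical(paste(back, collapse = ""), S_WALK)
})

test_that("weights follow |S*| - |S(h)*|", {
  expect_identical(hor_weight(S_WALK, "AB"), 6L)    # 29 - 23
  expect_identical(hor_weight(S_WALK, "EGF"), 8L)   # 29 - 21
  expect_identical(hor_weight(S_WALK, "ZZ"), 0L)
})

test_that("a planted HOR is selected by the greedy objective", {
  s <- rep(c("A", "B", "C"), 100)
  sel <- select_hor(s, hor_params())
  expect_false(is.null(sel))
  # the 3-mer unit up to rotation (ties resolved to the shortest candidate)
  expect_identical(length(sel$h), 3L)
  expect_identical(sort(sel$h), c("A", "B", "C"))
  # a monorun has no non-trivial candidate
  expect_null(select_hor(rep("A", 50), hor_params()))
})

test_that("select_hor enforces the monomer-containment requirement", {
  # bc is not selectable as a HOR when b and c are previous HORs
  s <- strsplit("CbcbaBcbcDbbDD", "")[[1]]
  sel <- select_hor(s, hor_params(), initial_alphabet = c("B", "C", "D"),
                    min_count = 1, min_weight = 1)
  expect_null(sel)  # bc/cb lack monomers; nothing else recurs
  sel2 <- select_hor(s, hor_params(), initial_alphabet = NULL,
                     min_count = 2, min_weight = 2, inclusive = TRUE)
  expect_identical(sel2$h, c("b", "c"))
})

test_that("forced substitutions reproduce the three-step worked chain", {
  dec <- hor_decompose(S_WALK, hor_params(),
                       canonical = list(a = "EGF", b = "AB", c = "Da"))
  expect_identical(format_symbol_string(dec$decomposition),
                   "CbcbaBcbcDb^2^D^2^")
  expect_identical(dec$hors$id, c("a", "b", "c"))
  expect_true(all(dec$hors$is_canonical))
  # per-step intermediate strings match the printed chain
  expect_identical(dec$log$n_after, c(22L, 17L, 14L))
  # lossless expansion back to the input
  flat <- expand_decomposition(dec$decomposition, dec$hors)
  expect_identical(paste(flat, collapse = ""), S_WALK)
})

test_that("the superHOR pass on the degree-stripped chain finds bc", {
  dec <- hor_decompose(S_WALK, hor_params(),
                       canonical = list(a = "EGF", b = "AB", c = "Da"))
  sup <- super_hor_decompose(dec)
  expect_identical(nrow(sup$hors), 1L)
  expect_identical(sup$hors$expansion[[1]], c("b", "c"))
  expect_true(sup$hors$is_super[1])
  expect_identical(sup$input, strsplit("CbcbaBcbcDbD", "")[[1]])
  # expansion of the superHOR decomposition restores the stripped string
  flat <- expand_decomposition(sup$decomposition, sup$hors)
  expect_identical(flat, sup$input)
})

test_that("degree stripping compacts power-split runs", {
  s <- parse_hor_string("ga^3^ga^15^ga^6^ga^4^ga^5^ga^39^", c("g", "a"))
  sup <- super_hor_decompose(s)
  expect_identical(nrow(sup$hors), 1L)
  expect_identical(sup$hors$expansion[[1]], c("g", "a"))
  # the degree-free superHOR string is (ga)(ga)...(ga); its run-length
  # encoding is the single element (ga)^6
  expect_identical(length(run_length_encode(sup$decomposition)), 1L)
  expect_identical(unique(sup$decomposition$symbols), sup$hors$id[1])
})

test_that("hor_decompose handles degenerate inputs", {
  # no recurrent substring: zero HORs, output equals input
  s <- LETTERS[1:10]
  dec <- hor_decompose(s, hor_params())
  expect_identical(nrow(dec$hors), 0L)
  expect_identical(horinfer:::ss_flat(dec$decomposition), s)
  # single symbol
  dec1 <- hor_decompose("A", hor_params())
  expect_identical(nrow(dec1$hors), 0L)
})

test_that("score identity holds at every substitution", {
  spec <- simulation_spec(n_monomers = 4, hor_pattern = c(1, 2, 3, 4),
                          n_units = 60, mutation_rate = 0, seed = 21)
  sim <- simulate_array(spec)
  b <- decompose(sim$sequence, sim$monomers)
  ms <- to_monostring(b)
  # insert structure so several HORs are found: append a variant segment
  s <- c(as.character(ms), rep(c("T01", "T02"), 12))
  dec <- hor_decompose(s, hor_params(min_count = 2, min_weight = 1))
  expect_gte(nrow(dec$hors), 2L)
  for (r in seq_len(nrow(dec$log))) {
    lg <- dec$log[r, ]
    # orbit shrinks by count*(|h|-1); score gains |h| on the set side
    expect_identical(lg$n_after, lg$n_before - lg$count * (lg$h_len - 1L))
    score_before <- lg$n_before
    score_after <- lg$n_after + lg$h_len
    expect_identical(score_after,
                     score_before - lg$count * (lg$h_len - 1L) + lg$h_len)
    expect_identical(lg$weight, lg$rle_before - lg$rle_after)
  }
  # full losslessness of the final decomposition
  flat <- expand_decomposition(dec$decomposition, dec$hors)
  expect_identical(flat, s)
  # every non-super HOR contains an original monomer
  for (e in dec$hors$expansion) {
    expect_true(any(e %in% c("T01", "T02", "T03", "T04")))
  }
})

test_that("a planted grammar is recovered up to rotation with variants", {
  spec <- simulation_spec(n_monomers = 5, n_units = 80, mutation_rate = 0.005,
                          seed = 22,
                          variant_units = list(list(pattern = c(1, 2, 4, 5),
                                                    freq = 0.05)))
  sim <- simulate_array(spec)
  res <- generate_monomers(sim$sequence, consensus(sim$monomers$seq)$consensus)
  dec <- hor_decompose(to_monostring(res$blocks), hor_params())
  expect_gte(nrow(dec$hors), 1L)
  top <- dec$hors[which.max(dec$hors$count), ]
  expect_identical(top$n_monomers, 5L)
  expect_identical(top$freq_class, "frequent")
  # lossless
  flat <- expand_decomposition(dec$decomposition, dec$hors)
  expect_identical(flat, as.character(to_monostring(res$blocks)))
})

test_that("HOR frequency classes follow the ceiling and rare thresholds", {
  hors <- tibble::tibble(id = c("x", "y", "z"), expansion = list("a", "b", "c"),
                         count = c(11L, 10L, 11L))
  dec400 <- symbol_string(rep(c("p", "q"), 200))      # |decomposition| = 400
  out <- classify_hor_frequency(hors, dec400, hor_params())
  expect_identical(out$freq_class[1], "frequent")     # 11 > 10
  expect_identical(out$freq_class[2], "rare")         # 10 <= rare_hor_count
  dec420 <- symbol_string(rep("p", 420))              # threshold 10.5
  out2 <- classify_hor_frequency(hors, run_length_encode(rep(c("p", "q"), 210)),
                                 hor_params())
  expect_identical(out2$freq_class[3], "frequent")
})

test_that("canonical HORs are kept even when absent from the string", {
  dec <- hor_decompose("ABABAB", hor_params(),
                       canonical = list(k = "CD"))
  expect_identical(dec$hors$id[1], "k")
  expect_identical(dec$hors$count[1], 0L)
  expect_true(dec$hors$is_canonical[1])
})

test_that("the non-monomeric token never enters a HOR", {
  s <- rep(c("A", "B", "?"), 30)
  dec <- hor_decompose(s, hor_params(min_count = 2, min_weight = 1))
  for (e in dec$hors$expansion) expect_false("?" %in% e)
  flat <- expand_decomposition(dec$decomposition, dec$hors)
  expect_identical(flat, s)
})
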