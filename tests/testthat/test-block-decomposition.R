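test_that("an exact tandem repeat decomposes into exact resolved blocks", {
  withr::with_seed(1, M <- rand_seq(40))
  arr <- paste(rep(M, 10), collapse = "")
  b <- decompose(arr, c(m1 = M))
  expect_identical(nrow(b), 10L)
  expect_true(all(b$div1 == 0))
  expect_true(all(b$status == "resolved"))
  expect_true(all(b$seq == M))
})

test_that("blocks tile the sequence with no gaps or overlaps", {
  withr::with_seed(2, {
    mons <- c(a = rand_seq(30), b = rand_seq(30))
    fx <- make_tandem(mons, c(1, 2, 1, 2, 1), 4, rate = 0.03, seed = 3)
    b <- decompose(fx$seq, mons)
    expect_identical(b$start[1], 0L)
    expect_identical(b$end[nrow(b)], nchar(fx$seq))
    expect_identical(b$start[-1], b$end[-nrow(b)])
    expect_identical(sum(b$end - b$start), nchar(fx$seq))
  })
})

test_that("alternating dissimilar monomers are recovered exactly", {
  # two monomers at ~30% mutual divergence, exact copies
  withr::with_seed(4, {
    m1 <- rand_seq(10)
    m2 <- mutate_subs(m1, 3L)
  })
  expect_gte(divergence(m1, m2), 0.2)
  arr <- paste0(m1, m2, m1, m2)
  b <- decompose(arr, c(m1 = m1, m2 = m2))
  expect_identical(nrow(b), 4L)
  expect_identical(b$best_monomer, c("m1", "m2", "m1", "m2"))
  expect_true(all(b$div1 == 0))
  # the DP achieves the brute-force optimum over all tilings
  expect_equal(attr(b, "alignment_score"),
               oracle_tiling_score(arr, c(m1, m2)))
})

test_that("the tiling DP matches the brute-force oracle on random instances", {
  withr::with_seed(5, {
    for (k in 1:8) {
      mons <- vapply(1:sample(1:3, 1), function(i) rand_seq(sample(4:8, 1)),
                     character(1))
      names(mons) <- paste0("m", seq_along(mons))
      n <- sample(20:60, 1)
      # arrays biased toward the monomers so blocks are non-trivial
      arr <- paste(vapply(1:ceiling(n / 5), function(i) {
        if (runif(1) < 0.7) mutate_rate(sample(mons, 1), 0.1)
        else rand_seq(sample(3:6, 1))
      }, character(1)), collapse = "")
      arr <- substr(arr, 1, n)
      b <- decompose(arr, mons)
      expect_equal(attr(b, "alignment_score"), oracle_tiling_score(arr, mons),
                   info = paste("case", k))
      expect_identical(sum(b$end - b$start), nchar(arr))
    }
  })
})

test_that("block classification applies the divergence thresholds", {
  p <- decomposition_params()
  expect_identical(classify_block(c(0.03, 0.45, 0.20), p),
                   c("resolved", "non_monomeric", "unresolved"))
  # boundary: thresholds are strict on both sides
  expect_identical(classify_block(c(0.05, 0.40), p),
                   c("unresolved", "unresolved"))
})

test_that("a block too diverged from every monomer is non-monomeric", {
  withr::with_seed(6, {
    m <- rand_seq(40)
    junk <- rand_seq(40)
  })
  expect_gt(divergence(m, junk), 0.4)
  b <- decompose(junk, c(m = m))
  expect_identical(nrow(b), 1L)
  expect_identical(b$status, "non_monomeric")
})

test_that("re-decomposition of a perfect repeat of inferred monomers is exact", {
  withr::with_seed(7, mons <- c(x = rand_seq(25), y = rand_seq(25)))
  arr <- paste(rep(paste0(mons["x"], mons["y"]), 6), collapse = "")
  b <- decompose(arr, mons)
  expect_true(all(b$div1 == 0))
})

test_that("monostring translation maps statuses to symbols", {
  withr::with_seed(8, {
    m1 <- rand_seq(30); m2 <- mutate_subs(m1, 10L)
    junk <- rand_seq(30)
  })
  arr <- paste0(m1, junk, m2)
  b <- decompose(arr, c(A = m1, B = m2))
  ms <- to_monostring(b)
  sym <- as.character(ms)
  expect_identical(sym[1], "A")
  expect_identical(sym[length(sym)], "B")
  expect_true("?" %in% sym)
  # empty block list
  empty <- to_monostring(b[0, ])
  expect_identical(length(as.character(empty)), 0L)
})

test_that("reverse-strand candidates are used only when enabled", {
  withr::with_seed(9, m <- rand_seq(40))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
  arr <- paste(rep(rc, 4), collapse = "")
  fwd <- decompose(arr, c(m = m))
  rev <- decompose(arr, c(m = m), decomposition_params(allow_reverse = TRUE))
  expect_true(all(fwd$div1 > 0.2))
  expect_true(all(rev$best_monomer == "m'"))
  expect_true(all(rev$div1 == 0))
})

test_that("non-monomeric runs are absorbed as added alphabet strings", {
  spec <- simulation_spec(n_monomers = 2, n_units = 20, mutation_rate = 0.005,
                          monomer_length = 100,
                          insertions = list(list(length = 350, after_unit = 10)),
                          seed = 10)
  sim <- simulate_array(spec)
  aug <- augment_with_nonmonomeric(sim$sequence, sim$monomers)
  expect_identical(sum(aug$monomers$is_nonmonomeric), 1L)
  nm_id <- aug$monomers$id[aug$monomers$is_nonmonomeric]
  hit <- aug$blocks[aug$blocks$best_monomer == nm_id, ]
  expect_identical(nrow(hit), 1L)
  expect_lt(hit$div1, 0.05)
  # truth interval of the insertion is recovered
  ins <- sim$truth[sim$truth$type == "insertion", ]
  expect_lt(abs(hit$start - ins$start), 30)
  expect_lt(abs(hit$end - ins$end), 30)
})

test_that("arrays without non-monomeric blocks pass through unchanged", {
  withr::with_seed(11, m <- rand_seq(40))
  arr <- paste(rep(m, 5), collapse = "")
  aug <- augment_with_nonmonomeric(arr, c(m = m))
  expect_identical(nrow(aug$monomers), 1L)
  expect_identical(aug$blocks$status, rep("resolved", 5L))
})

test_that("two identical insertions yield one added string matching both", {
  spec <- simulation_spec(n_monomers = 2, n_units = 24, mutation_rate = 0.005,
                          monomer_length = 100, seed = 12,
                          insertions = list(list(length = 300, after_unit = 8),
                                            list(length = 300, after_unit = 16)))
  sim <- simulate_array(spec)
  # plant the *same* insertion twice: rebuild with a copy
  ins_rows <- which(sim$truth$type == "insertion")
  s <- sim$sequence
  first <- substr(s, sim$truth$start[ins_rows[1]] + 1, sim$truth$end[ins_rows[1]])
  s2 <- paste0(substr(s, 1, sim$truth$start[ins_rows[2]]), first,
               substr(s, sim$truth$end[ins_rows[2]] + 1, nchar(s)))
  aug <- augment_with_nonmonomeric(s2, sim$monomers)
  expect_identical(sum(aug$monomers$is_nonmonomeric), 1L)
  nm_id <- aug$monomers$id[aug$monomers$is_nonmonomeric]
  expect_identical(nrow(aug$blocks[aug$blocks$best_monomer == nm_id, ]), 2L)
})
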