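test_that("block-graph edges follow the divergence threshold", {
  withr::with_seed(1, b <- rand_seq(40))
  bg <- build_block_graph(c(b, b), 0.025)
  expect_identical(nrow(bg$edges), 1L)
  expect_identical(max(bg$sizes), 2L)
  # blocks at ~10% divergence, threshold 2.5%: no edges
  withr::with_seed(2, b2 <- mutate_subs(b, 4L))
  bg2 <- build_block_graph(c(b, b2), 0.025)
  expect_identical(nrow(bg2$edges), 0L)
  expect_identical(bg2$sizes, c(1L, 1L))
})

test_that("two planted clusters give two components with the planted sizes", {
  withr::with_seed(3, {
    A <- rand_seq(171)
    B <- mutate_subs(A, 50L)  # ~30% apart
    blocks <- c(vapply(1:60, function(i) mutate_rate(A, 0.005), character(1)),
                vapply(1:40, function(i) mutate_rate(B, 0.005), character(1)))
  })
  bg <- build_block_graph(blocks, 0.025)
  expect_identical(length(bg$sizes), 2L)
  expect_identical(sort(bg$sizes, decreasing = TRUE), c(60L, 40L))
})

test_that("the prefiltered block graph equals the all-pairs oracle", {
  withr::with_seed(4, {
    A <- rand_seq(120); B <- mutate_subs(A, 40L)
    blocks <- c(vapply(1:250, function(i) mutate_rate(A, 0.01), character(1)),
                vapply(1:250, function(i) mutate_rate(B, 0.01), character(1)))
  })
  got <- build_block_graph(blocks, 0.025, brute_force_below = 0L)
  oracle <- oracle_block_graph_edges(blocks, 0.025)
  got_keys <- sort(paste(got$edges$from, got$edges$to))
  oracle_keys <- sort(paste(oracle[, 1], oracle[, 2]))  # upper.tri: row < col
  expect_identical(got_keys, oracle_keys)
})

test_that("an exact tandem repeat is resolved by its own monomer at once", {
  withr::with_seed(5, M <- rand_seq(171))
  arr <- paste(rep(M, 50), collapse = "")
  res <- generate_monomers(arr, M)
  expect_identical(nrow(res$monomers), 1L)
  expect_identical(res$monomers$seq, M)
  expect_identical(res$iterations, 1L)
  expect_identical(sum(res$blocks$status == "resolved"), 50L)
  expect_true(res$converged)
})

test_that("planted monomers are recovered from the array consensus start", {
  spec <- simulation_spec(n_monomers = 2, n_units = 40, mutation_rate = 0.01,
                          seed = 6)
  sim <- simulate_array(spec)
  init <- consensus(sim$monomers$seq)$consensus
  res <- generate_monomers(sim$sequence, init)
  expect_identical(sum(res$monomers$freq_class == "frequent"), 2L)
  tc <- truth_compare(res$blocks, sim$truth, res$monomers, sim$monomers)
  expect_true(all(tc$monomer_matches$divergence <= 0.01))
  expect_gte(tc$recall, 0.99)
  # termination predicate: resolved fraction above threshold, rest non-monomeric
  expect_gt(mean(res$blocks$status == "resolved"),
            res$params$fraction_resolved_blocks)
  expect_identical(sum(res$blocks$status == "unresolved"), 0L)
})

test_that("the final monomer set is a fixed point of consensus recomputation", {
  spec <- simulation_spec(n_monomers = 3, n_units = 30, mutation_rate = 0.01,
                          seed = 7)
  sim <- simulate_array(spec)
  init <- consensus(sim$monomers$seq)$consensus
  res <- generate_monomers(sim$sequence, init)
  for (i in seq_len(nrow(res$monomers))) {
    rb <- res$blocks$seq[res$blocks$best_monomer == res$monomers$id[i] &
                           res$blocks$status == "resolved"]
    expect_identical(consensus(horinfer:::evenly_spaced(rb, 100L))$consensus,
                     res$monomers$seq[i])
  }
})

test_that("resolved-block counts are non-decreasing across iterations", {
  spec <- simulation_spec(n_monomers = 3, n_units = 30, mutation_rate = 0.01,
                          seed = 8)
  sim <- simulate_array(spec)
  res <- generate_monomers(sim$sequence, consensus(sim$monomers$seq)$consensus)
  expect_true(all(diff(res$log$n_resolved) >= 0))
  expect_named(res$log,
               c("iter", "n_resolved", "n_unresolved", "n_non_monomeric",
                 "largest_component", "radius", "separation_prev",
                 "monomer_length"))
})

test_that("a low-copy planted monomer is reported as rare", {
  # 3-monomer HOR plus 4 copies of a fourth monomer
  withr::with_seed(9, {
    anc <- rand_seq(171)
    mons <- vapply(1:4, function(i) mutate_subs(anc, 21L), character(1))
    names(mons) <- paste0("p", 1:4)
  })
  main <- make_tandem(mons, c(1, 2, 3), 60, rate = 0.005, seed = 10)
  extra <- make_tandem(mons, c(4, 1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4), 1,
                       rate = 0.005, seed = 11)
  arr <- paste0(main$seq, extra$seq)
  res <- generate_monomers(arr, consensus(mons)$consensus)
  expect_identical(sum(res$monomers$freq_class == "frequent"), 3L)
  rare <- res$monomers[res$monomers$freq_class == "rare", ]
  expect_identical(nrow(rare), 1L)
  expect_identical(rare$count, 4L)
  # consensus of only four noisy copies can differ from the planted monomer
  # by a couple of tie-broken sites
  expect_lte(divergence(rare$seq, mons[["p4"]]), 0.02)
})

test_that("monomer statistics implement the counting and class rules", {
  withr::with_seed(12, {
    m1 <- rand_seq(50); m2 <- mutate_subs(m1, 15L)
  })
  blocks <- tibble::tibble(
    seq_id = "s", start = 0L, end = 1L,
    best_monomer = c(rep("m1", 11), rep("m2", 5), rep("m1", 384)),
    second_monomer = NA_character_, div1 = 0.01, div2 = NA_real_,
    status = c(rep("resolved", 16), rep("resolved", 384)),
    seq = c(rep(m1, 11), rep(m2, 5), rep(m1, 384)))
  st <- monomer_stats(c(m1 = m1, m2 = m2), blocks)
  # 400 blocks, ceiling 40: threshold 10; m1 count 395 frequent
  expect_identical(st$freq_class[st$id == "m1"], "frequent")
  # count 5 does not exceed rare_monomer_count = 5: rare
  expect_identical(st$count[st$id == "m2"], 5L)
  expect_identical(st$freq_class[st$id == "m2"], "rare")
  expect_identical(st$radius, c(0L, 0L))
  expect_identical(st$separation_ratio, c(Inf, Inf))
  expect_identical(st$separation[1], as.integer(adist(m1, m2)))
  # single monomer: separation undefined
  st1 <- monomer_stats(c(m1 = m1), blocks[blocks$best_monomer == "m1", ])
  expect_true(is.na(st1$separation))
})

test_that("exact and near-exact hybrids are detected, far candidates are not", {
  withr::with_seed(13, {
    anc <- rand_seq(171)
    X <- mutate_subs(anc, 21L); Y <- mutate_subs(anc, 21L)
    far <- rand_seq(171)
  })
  parents <- c(X = X, Y = Y)
  M <- paste0(substr(X, 1, 68), substring(Y, 69))
  h <- detect_hybrids(c(M = M), parents, expected_length = 171)
  expect_true(h$is_hybrid)
  expect_identical(h$hybrid_divergence, 0)
  expect_identical(h$parent_x, "X")
  expect_identical(h$parent_y, "Y")
  expect_identical(h$prefix_len + h$suffix_len, 171L)
  # one substitution: divergence 1/171, still within 1%
  Mc <- M; substr(Mc, 40, 40) <- setdiff(BASES, substr(M, 40, 40))[1]
  h2 <- detect_hybrids(c(Mc = Mc), parents, expected_length = 171)
  expect_true(h2$is_hybrid)
  expect_equal(h2$hybrid_divergence, 1 / 171, tolerance = 1e-12)
  # an unrelated sequence is not annotated
  h3 <- detect_hybrids(c(far = far), parents, expected_length = 171)
  expect_false(h3$is_hybrid)
  expect_gt(h3$hybrid_divergence, 0.2)
})

test_that("exhaustive hybrid search agrees with the windowed default", {
  withr::with_seed(14, {
    anc <- rand_seq(60)
    X <- mutate_subs(anc, 8L); Y <- mutate_subs(anc, 8L)
  })
  M <- paste0(substr(X, 1, 25), substring(Y, 31))  # i + j = 55 != |M| is fine
  hw <- detect_hybrids(c(M = M), c(X = X, Y = Y), expected_length = nchar(M))
  he <- detect_hybrids(c(M = M), c(X = X, Y = Y), exhaustive = TRUE)
  expect_identical(hw$hybrid_divergence, 0)
  expect_identical(he$hybrid_divergence, 0)
})
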