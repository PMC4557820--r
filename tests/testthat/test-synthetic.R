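test_that("simulated trees are seeded, sized, and multiplier-aware", {
  t1 <- simulate_tree(10, seed = 81)
  t2 <- simulate_tree(10, seed = 81)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 10L)
  # rooted binary tree: 2n - 2 edges
  expect_equal(nrow(t1$edge), 2 * 10 - 2)

  t3 <- simulate_tree(10, seed = 81, rate_multipliers = c(t4 = 5))
  e <- which(t1$edge[, 2] == match("t4", t1$tip.label))
  expect_equal(t3$edge.length[e], 5 * t1$edge.length[e])

  t4 <- simulate_tree(4, seed = 82)
  expect_equal(ape::unroot(t4)$Nnode, 2L)  # one internal edge unrooted
})

test_that("zero-length branches yield identical, all-constant sequences", {
  tree <- balanced8()
  tree$edge.length[] <- 0
  aln <- simulate_structured_alignment(tree, sim_config(n_raa = 1),
                                       seed = 83)
  cnt <- count_site_patterns(aln)
  expect_equal(cnt$n_constant, cnt$n_columns)
  expect_equal(nrow(unique(aln$seqs)), 1L)
})

test_that("compensation tally tracks the planted q", {
  tree <- balanced8(tip = 0.6, inner = 0.5, deep = 0.5)
  aln <- simulate_structured_alignment(
    tree, sim_config(stem_pairs = 250, q = 1), seed = 84)
  tru <- attr(aln, "truth")
  expect_equal(tru$stem_compensated / tru$stem_events, 1)

  aln0 <- simulate_structured_alignment(
    tree, sim_config(stem_pairs = 250, q = 0.5), seed = 85)
  tru0 <- attr(aln0, "truth")
  frac <- tru0$stem_compensated / tru0$stem_events
  se <- sqrt(0.25 / tru0$stem_events)
  expect_lt(abs(frac - 0.5), 4 * se)
})

test_that("truth records allow independent recomputation of RAA lengths", {
  tree <- simulate_tree(6, seed = 86)
  aln <- simulate_structured_alignment(tree, sim_config(n_raa = 2),
                                       seed = 87)
  tru <- attr(aln, "truth")
  blocks <- extract_raa_blocks(aln)
  for (k in seq_along(blocks)) {
    expect_equal(nchar(blocks[[k]]$seqs), tru$raa_lengths[[k]])
  }
  # generators are deterministic under fixed seed
  aln2 <- simulate_structured_alignment(tree, sim_config(n_raa = 2),
                                        seed = 87)
  expect_identical(aln$seqs, aln2$seqs)
  expect_identical(aln$mask, aln2$mask)
})

test_that("GC-rich low-deletion lineages plant a positive GC-length correlation", {
  nwk <- paste0("(", paste(sprintf("t%d:0.5", 1:12), collapse = ","), ");")
  star <- ape::read.tree(text = nwk)
  gc <- stats::setNames(rep(1, 6), paste0("t", 1:6))
  aln <- simulate_structured_alignment(
    star, sim_config(n_raa = 5, raa_base_length = 40, indel_rate = 0.8,
                     gc_rich_lineages = gc), seed = 95)
  rho <- gc_length_correlation(base_composition(aln$seqs))
  expect_gt(rho$rho, 0.3)
  # without the coupling the same conditions give no systematic signal
  aln0 <- simulate_structured_alignment(
    star, sim_config(n_raa = 5, raa_base_length = 40, indel_rate = 0.8),
    seed = 95)
  rho0 <- gc_length_correlation(base_composition(aln0$seqs))
  expect_lt(abs(rho0$rho), 0.9)
})

test_that("bootstrap conflict frequencies follow the multinomial spec", {
  ref <- ape::read.tree(text = "((a,b),(c,d),e);")
  all_true <- simulate_bootstrap_tree_set(
    ref, list(list(clade = c("a", "b"), f1 = 1, f2 = 0)), 200, seed = 88)
  sys <- split_frequencies(all_true)
  expect_equal(unname(sys$freq["c|d|e"]), 1)
  ct <- internode_certainty(ref, all_true)
  expect_equal(ct$edges$ic, rep(1, 2))

  half <- simulate_bootstrap_tree_set(
    ref, list(list(clade = c("a", "b"), f1 = 0.5, f2 = 0.5)), 400,
    seed = 89)
  sysh <- split_frequencies(half)
  expect_lt(abs(sysh$freq[["c|d|e"]] - 0.5), 3 * sqrt(0.25 / 400))
  expect_error(simulate_bootstrap_tree_set(
    ref, list(list(clade = c("a", "e"), f1 = 0.5, f2 = 0.5)), 10),
    "internode")
})

test_that("posterior samples respect jitter and multipliers", {
  tree <- balanced8()
  still <- simulate_posterior_sample(tree, jitter_sd = 0, n = 20,
                                     seed = 90)
  prof <- pathlength_profiles(still, clade = tree$tip.label)
  expect_equal(apply(prof, 2, stats::sd), rep(0, 8),
               ignore_attr = TRUE)

  s1 <- simulate_posterior_sample(tree, jitter_sd = 0.2, n = 5, seed = 91)
  s2 <- simulate_posterior_sample(tree, jitter_sd = 0.2, n = 5, seed = 91)
  expect_identical(lapply(s1, `[[`, "edge.length"),
                   lapply(s2, `[[`, "edge.length"))
})

test_that("simulated traces have the planted moments", {
  t0 <- simulate_trace(-100, 0, 50, seed = 92)
  expect_equal(t0$lnl, rep(-100, 50))
  t1 <- simulate_trace(-1000, 5, 4000, seed = 93)
  expect_lt(abs(mean(t1$lnl) + 1000), 5 * 5 / sqrt(4000) * 4)
  expect_lt(abs(stats::sd(t1$lnl) - 5), 0.5)
})

test_that("a full synthetic run pushes through the whole pipeline", {
  tree <- balanced8(tip = 0.05, inner = 0.08, deep = 0.1)
  aln <- simulate_structured_alignment(
    tree, sim_config(stem_pairs = 30, loop_length = 60, n_raa = 2,
                     raa_base_length = 25), seed = 94)
  # partition diagnostics
  loops <- extract_partition(aln, "LOOP")
  prof <- base_composition(loops, "loop")
  expect_gt(sum(prof$A) / sum(prof$length), 0.3)
  expect_equal(count_site_patterns(aln)$n_columns, ncol(aln$seqs))
  # RAA rescue
  blocks <- extract_raa_blocks(aln)
  aligned <- lapply(blocks, align_block, guide = tree)
  cc <- concatenate_blocks(aligned)
  mp <- random_similarity_mask(cc$aln, reps = 120, seed = 1)
  filtered <- apply_mask(cc$aln, mp)
  expect_lte(ncol(filtered), ncol(cc$aln))
  # masking keeps part of the signal and preferentially drops the
  # gap-riddled indel stretches
  expect_gt(mean(mp$keep), 0.15)
  gap_kept <- mean(cc$aln[, mp$keep] == "-")
  gap_dropped <- mean(cc$aln[, !mp$keep] == "-")
  expect_lt(gap_kept, gap_dropped)
  # tree-side signal
  boots <- simulate_bootstrap_tree_set(
    ape::unroot(tree), list(list(clade = c("t1", "t2"), f1 = 0.9,
                                 f2 = 0.1)),
    n_trees = 200, seed = 2)
  ct <- internode_certainty(ape::unroot(tree), boots)
  expect_true(all(ct$edges$ic > 0.2))
  # rates
  post <- simulate_posterior_sample(tree, multipliers = c(t7 = 8),
                                    jitter_sd = 0.1, n = 300, seed = 3)
  rr <- relative_rates_test(pathlength_profiles(post,
                                                clade = tree$tip.label))
  expect_identical(rr$terminal[rr$fast], "t7")
})
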