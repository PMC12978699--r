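test_that("p_six is the exact 6-cut fraction of the bridge set", {
  expect_equal(p_six(canonical_cyst(3)), 2 / 7)
  # leaf_first 7-cell topology: its three newest bridges each sever one cell,
  # leaving a 6-cell product (value frozen from the component oracle)
  g7 <- partial_cyst(7)
  expect_equal(p_six(g7),
               sum(oracle_break_pairs(g7)[, 2] == 6L) / n_bridges(g7))
  expect_equal(p_six(g7), 3 / 6)
  # a 6-cell cyst has no proper 6-cell fragment
  expect_equal(p_six(partial_cyst(6)), 0)
})

test_that("random breakage partitions the cyst and is seed-reproducible", {
  g8 <- canonical_cyst(3)
  fr <- random_break(g8, seed = 11)
  expect_equal(sort(c(cyst_cells(fr[[1]]), cyst_cells(fr[[2]]))),
               cyst_cells(g8))
  expect_equal(sum(vapply(fr, n_cells, integer(1))), 8L)
  fr2 <- random_break(g8, seed = 11)
  expect_identical(lapply(fr, export_edge_list), lapply(fr2, export_edge_list))
  expect_identical(attr(fr, "broken_bridge"), attr(fr2, "broken_bridge"))
  # each fragment is itself a valid cyst tree
  for (f in fr) expect_silent(validate_cyst_graph(f))

  # empirical 6-cell frequency approaches the enumerated p_six
  set.seed(202)
  draws <- 4000L
  hits <- sum(vapply(seq_len(draws), function(i) {
    any(vapply(random_break(g8), n_cells, integer(1)) == 6L)
  }, logical(1)))
  p <- p_six(g8)
  se <- sqrt(p * (1 - p) / draws)
  expect_lt(abs(hits / draws - p), 4 * se)
})

test_that("the programmed break releases the pro-oocyte in a 6-cell fragment", {
  g8 <- canonical_cyst(3)
  fr <- programmed_break(g8)
  expect_equal(size_multiset(fr), c(2L, 6L))
  six <- fr[[which(vapply(fr, n_cells, integer(1)) == 6L)]]
  expect_true(max_degree_cell(g8) %in% cyst_cells(six))
  # deterministic tie-break: of the two 2|6 bridges the one with the
  # smallest endpoints breaks
  expect_equal(sort(attr(fr, "broken_bridge")), c(1L, 3L))

  expect_error(programmed_break(partial_cyst(6)), "no six-cell cut")
  # the leaf_first 10-cell topology has no 6-cell cut at all (oracle-checked)
  g10 <- partial_cyst(10)
  expect_false(any(oracle_break_pairs(g10) == 6L))
  expect_error(programmed_break(g10), "no six-cell cut")
})

test_that("quartet fragmentation of a 32-cell clone yields four 6s and four 2s", {
  out <- quartet_fragmentation(canonical_cyst(5))
  expect_equal(out$fragment_multiset, c(`2` = 4L, `6` = 4L))
  expect_equal(out$oocyte_count, 4L)
  # cell conservation
  sizes <- vapply(out$fragments, n_cells, integer(1))
  expect_equal(sum(sizes), 32L)
  for (f in out$fragments) expect_silent(validate_cyst_graph(f))
  # the four 6-cell derivatives partition disjointly
  all_cells <- sort(unlist(lapply(out$fragments, cyst_cells)))
  expect_equal(all_cells, 1:32)

  expect_error(quartet_fragmentation(canonical_cyst(4)), "32-cell")
  # a 32-cell tree whose bridge-creation history is not the canonical
  # 1/2/4/8/16 round profile is rejected
  g <- canonical_cyst(5)
  g$bridges$round_created[g$bridges$round_created == 2L][1] <- 3L
  expect_error(quartet_fragmentation(g), "not a canonical")
})

test_that("quartet fragmentation is invariant to cell relabeling", {
  g <- canonical_cyst(5)
  set.seed(7)
  perm <- stats::setNames(sample(101:132), 1:32)
  out <- quartet_fragmentation(relabel_cyst(g, perm))
  expect_equal(out$fragment_multiset, c(`2` = 4L, `6` = 4L))
})

test_that("clone simulation follows the fragmentation schedule", {
  whole <- simulate_clone(sim_config(fragmentation_schedule = "none"))
  expect_equal(size_multiset(whole$fragments), 32L)
  expect_equal(whole$oocyte_count, 0L)

  quartet <- simulate_clone(sim_config(fragmentation_schedule = "quartet"))
  expect_equal(quartet$fragment_multiset, c(`2` = 4L, `6` = 4L))
  expect_equal(quartet$oocyte_count, 4L)

  # regression fixture: the eight_cell schedule breaks the first 8-cell cyst
  # into 6+2, after which the doubled fragments no longer offer a six-cell
  # cut until the 2-cell side regrows to 8 cells
  eight <- simulate_clone(sim_config(fragmentation_schedule = "eight_cell"))
  expect_equal(size_multiset(eight$fragments), c(2L, 6L, 24L))
  expect_equal(sum(size_multiset(eight$fragments)), 32L)
  expect_equal(eight$oocyte_count, 1L)

  # fewer rounds, no breakage: plain powers of two
  expect_equal(size_multiset(simulate_clone(sim_config(rounds = 3))$fragments),
               8L)
})
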