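test_that("founder and single divisions behave as incomplete cytokinesis", {
  g <- cyst_founder()
  expect_equal(n_cells(g), 1L)
  expect_equal(n_bridges(g), 0L)
  expect_equal(degree_of(g, 1L), 0L)
  expect_silent(validate_cyst_graph(g))

  g2 <- divide_round(g)
  expect_equal(n_cells(g2), 2L)
  expect_equal(n_bridges(g2), 1L)
  expect_equal(sort(unname(cyst_degrees(g2))), c(1L, 1L))

  # hand-applied retention rule: after two rounds cell 1 and 2 each hold two
  # bridges, the two newest cells one each
  g4 <- divide_round(g2)
  expect_equal(sort(unname(cyst_degrees(g4))), c(1L, 1L, 2L, 2L))

  expect_error(divide_round(g2, integer()), "at least one divider")
  expect_error(divide_round(g2, c(1L, 7L)), "member cells")
  expect_error(divide_round(g2, c(1L, 1L)), "duplicate")
})

test_that("canonical cysts have the maximally branched topology", {
  for (r in 0:5) {
    g <- canonical_cyst(r)
    expect_equal(n_cells(g), 2L^r)
    expect_equal(n_bridges(g), 2L^r - 1L)
    expect_true(oracle_is_tree(g))
    expect_silent(validate_cyst_graph(g))
    deg <- cyst_degrees(g)
    if (r >= 1) expect_equal(max(deg), r)
    if (r >= 2) expect_equal(sum(deg == 1L), 2L^(r - 1L))
    # handshake lemma
    expect_equal(sum(deg), 2L * n_bridges(g))
  }
  expect_equal(sort(unname(cyst_degrees(canonical_cyst(3)))),
               c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L))
  g16 <- canonical_cyst(4)
  expect_equal(max(cyst_degrees(g16)), 4L)
  expect_equal(sum(cyst_degrees(g16) == 1L), 8L)
  expect_equal(max_degree_cell(canonical_cyst(3)), 1L)
  expect_equal(degree_of(canonical_cyst(3), 1L), 3L)
})

test_that("partial cysts reach any intermediate size and stay trees", {
  for (n in 5:32) {
    g <- partial_cyst(n)
    expect_equal(n_cells(g), n)
    expect_equal(n_bridges(g), n - 1L)
    expect_true(oracle_is_tree(g))
  }
  # power of two needs no partial round
  expect_equal(export_edge_list(partial_cyst(8)),
               export_edge_list(canonical_cyst(3)))
  # leaf_first is deterministic
  expect_identical(export_edge_list(partial_cyst(11)),
                   export_edge_list(partial_cyst(11)))
  # random_subset is seed-reproducible but seed-dependent
  expect_identical(export_edge_list(partial_cyst(11, "random_subset", seed = 4)),
                   export_edge_list(partial_cyst(11, "random_subset", seed = 4)))
  g <- partial_cyst(13, "random_subset", seed = 1)
  expect_equal(n_cells(g), 13L)
  expect_true(oracle_is_tree(g))
})

test_that("fragment sizes partition the cyst and match the component oracle", {
  g8 <- canonical_cyst(3)
  # the round-1 bridge halves the cyst
  expect_equal(fragment_sizes(g8, c(1, 2)), c(4L, 4L))
  # every round-3 bridge severs a single cell
  r3 <- g8$bridges[g8$bridges$round_created == 3L, ]
  for (i in seq_len(nrow(r3)))
    expect_equal(fragment_sizes(g8, c(r3$cell_a[i], r3$cell_b[i])), c(1L, 7L))
  expect_equal(fragment_sizes(divide_round(cyst_founder()), c(1, 2)),
               c(1L, 1L))
  expect_error(fragment_sizes(g8, c(3, 4)), "bridge not in graph")

  # exhaustive enumeration agrees with the igraph component oracle on all
  # canonical and partial topologies up to 32 cells
  for (g in c(lapply(1:5, canonical_cyst), lapply(c(7, 9, 10, 13, 27), partial_cyst))) {
    enum <- enumerate_break_outcomes(g)
    expect_equal(unname(as.matrix(enum[, c("size_small", "size_large")])),
                 unname(oracle_break_pairs(g)))
    expect_true(all(enum$size_small + enum$size_large == n_cells(g)))
  }
})

test_that("the canonical 8-cell cyst has the published break-size multiset", {
  enum <- enumerate_break_outcomes(canonical_cyst(3))
  pairs <- sprintf("(%d,%d)", enum$size_small, enum$size_large)
  expect_equal(sort(pairs),
               sort(c(rep("(1,7)", 4), rep("(2,6)", 2), "(4,4)")))
  enum4 <- enumerate_break_outcomes(canonical_cyst(2))
  expect_equal(sort(enum4$size_small), c(1L, 1L, 2L))
})

test_that("exports round-trip losslessly", {
  g <- partial_cyst(10)
  # edge list round trip: isomorphic graph, identical bridge metadata
  back <- read_edge_list(lines = export_edge_list(g))
  expect_true(igraph::isomorphic(oracle_igraph(g), oracle_igraph(back)))
  expect_equal(back$bridges[order(back$bridges$cell_a, back$bridges$cell_b), ],
               g$bridges[order(g$bridges$cell_a, g$bridges$cell_b), ])
  tmp <- withr::local_tempfile(fileext = ".tsv")
  export_edge_list(g, tmp)
  expect_equal(read_edge_list(tmp)$bridges, back$bridges)

  # JSON round trip is exact
  g2 <- cyst_from_json(txt = cyst_to_json(g))
  expect_equal(g2$cells, g$cells)
  expect_equal(g2$bridges, g$bridges)

  # newick carries the full parent -> daughter history
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = export_newick(canonical_cyst(3)))
  expect_equal(sort(as.integer(tr$tip.label)), c(5L, 6L, 7L, 8L))
  expect_equal(sort(as.integer(tr$node.label)), c(1L, 2L, 3L, 4L))
  # branch length = creation round of the cell below the branch
  tips <- match(as.character(c(5, 6, 7, 8)), tr$tip.label)
  lens <- tr$edge.length[match(tips, tr$edge[, 2])]
  expect_equal(lens, rep(3, 4))
})
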