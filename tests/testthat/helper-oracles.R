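# Independent oracles used to cross-check the package's own graph routines.
# Connectivity and component queries go through igraph here, so the checks do
# not share code with the package's internal traversal.

oracle_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(g$bridges$cell_a),
                   to = as.character(g$bridges$cell_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$cells$cell_id)))
}

# Fragment-size pairs from deleting each edge in turn, via igraph components.
oracle_break_pairs <- function(g) {
  ig <- oracle_igraph(g)
  t(vapply(seq_len(igraph::ecount(ig)), function(i) {
    comp <- igraph::components(igraph::delete_edges(ig, i))
    sort(as.integer(comp$csize))
  }, integer(2)))
}

oracle_is_tree <- function(g) {
  ig <- oracle_igraph(g)
  igraph::is_connected(ig) &&
    igraph::ecount(ig) == igraph::vcount(ig) - 1L
}

# Exact Poisson-binomial pmf by enumerating all 2^n outcome vectors.
oracle_poisson_binom <- function(probs) {
  n <- length(probs)
  pmf <- numeric(n + 1L)
  for (mask in 0:(2^n - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    pmf[sum(bits) + 1L] <- pmf[sum(bits) + 1L] +
      prod(ifelse(bits == 1L, probs, 1 - probs))
  }
  pmf
}

# Relabel the cells of a cyst by a permutation (for isomorphism invariance).
relabel_cyst <- function(g, perm) {
  # perm: named integer vector old id -> new id
  key <- function(x) unname(perm[as.character(x)])
  g$cells$cell_id <- key(g$cells$cell_id)
  g$cells$parent <- key(g$cells$parent)
  g$bridges$cell_a <- key(g$bridges$cell_a)
  g$bridges$cell_b <- key(g$bridges$cell_b)
  g
}

size_multiset <- function(fragments) {
  sort(vapply(fragments, n_cells, integer(1)))
}
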