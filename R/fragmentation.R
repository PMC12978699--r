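#' Fragment sizes produced by removing one bridge
#'
#' Breaking a single intercellular bridge splits the cyst tree into exactly
#' two connected fragments; this returns their sizes.
#'
#' @param g A `cyst_graph`.
#' @param bridge Length-2 vector `c(cell_a, cell_b)` identifying the bridge
#'   (either endpoint order).
#' @return Integer vector `c(size_small, size_large)`; the two always sum to
#'   `n_cells(g)`.
#' @export
#' @examples
#' g <- canonical_cyst(3)
#' fragment_sizes(g, c(1, 2))  # the round-1 bridge splits 4 | 4
fragment_sizes <- function(g, bridge) {
  i <- bridge_index(g, bridge)
  side <- reachable_cells(g, g$bridges$cell_a[i], drop_bridge = i)
  s <- length(side)
  sort(c(s, n_cells(g) - s))
}

#' Enumerate all single-bridge breakage outcomes
#'
#' Exhaustively removes each bridge in turn and records the two fragment
#' sizes its removal produces. For the canonical 8-cell cyst this yields the
#' size-pair multiset \{(1,7) x4, (2,6) x2, (4,4) x1\}: only 2 of the 7
#' bridges release a 6-cell derivative.
#'
#' @param g A `cyst_graph` with at least 2 cells.
#' @return A data frame with one row per bridge: `cell_a`, `cell_b`,
#'   `round_created`, `size_small`, `size_large`.
#' @export
enumerate_break_outcomes <- function(g) {
  stopifnot(n_cells(g) >= 2L)
  out <- g$bridges
  sizes <- t(vapply(seq_len(nrow(out)), function(i) {
    side <- reachable_cells(g, out$cell_a[i], drop_bridge = i)
    s <- length(side)
    sort(c(s, n_cells(g) - s))
  }, integer(2)))
  out$size_small <- sizes[, 1L]
  out$size_large <- sizes[, 2L]
  out
}

#' Probability that a random break releases a 6-cell fragment
#'
#' Under the random-breakage null a single bridge is removed uniformly at
#' random; `p_six()` is the exact fraction of bridges whose removal yields a
#' fragment of exactly 6 cells. For the canonical 8-cell cyst this is 2/7.
#'
#' @param g A `cyst_graph` with at least 2 cells.
#' @return A probability (exact ratio of small integers).
#' @export
#' @examples
#' p_six(canonical_cyst(3))  # 2/7
p_six <- function(g) {
  out <- enumerate_break_outcomes(g)
  sum(out$size_small == 6L | out$size_large == 6L) / nrow(out)
}

#' Break one bridge uniformly at random
#'
#' @param g A `cyst_graph` with at least 2 cells.
#' @param seed Optional integer seed; otherwise the current RNG state is
#'   used.
#' @return A list of two `cyst_graph` fragments (smaller first; ties broken
#'   by smallest contained cell id) plus the removed bridge as attribute
#'   `"broken_bridge"`.
#' @export
random_break <- function(g, seed = NULL) {
  stopifnot(n_cells(g) >= 2L)
  if (!is.null(seed)) withr::local_seed(seed)
  i <- sample.int(nrow(g$bridges), 1L)
  break_at(g, i)
}

# Split at bridge row index i into the two fragment graphs.
break_at <- function(g, i) {
  side_a <- reachable_cells(g, g$bridges$cell_a[i], drop_bridge = i)
  side_b <- setdiff(g$cells$cell_id, side_a)
  frags <- list(induced_subcyst(g, side_a), induced_subcyst(g, side_b))
  sz <- vapply(frags, n_cells, integer(1))
  ord <- order(sz, vapply(frags, function(f) min(f$cells$cell_id), integer(1)))
  frags <- frags[ord]
  attr(frags, "broken_bridge") <- c(g$bridges$cell_a[i], g$bridges$cell_b[i])
  frags
}

#' Programmed break at the microtubule-gap bridge
#'
#' Deterministic fragmentation rule for the non-random breakage observed in
#' vivo: among the bridges whose removal releases a 6-cell fragment, break
#' the one whose 6-cell side contains the most-branched cell (the
#' fusome-enriched pro-oocyte); remaining ties are broken by smallest
#' creation round, then smallest endpoint ids.
#'
#' @param g A `cyst_graph`.
#' @param seed Unused; present for interface symmetry with [random_break()].
#' @return As [random_break()]: a list of the two fragments.
#' @export
#' @examples
#' frags <- programmed_break(canonical_cyst(3))
#' vapply(frags, n_cells, integer(1))  # 2 6
programmed_break <- function(g, seed = NULL) {
  out <- enumerate_break_outcomes(g)
  cand <- which(out$size_small == 6L | out$size_large == 6L)
  if (length(cand) == 0L) stop("no six-cell cut")
  star <- max_degree_cell(g)
  has_star <- vapply(cand, function(i) {
    side <- reachable_cells(g, g$bridges$cell_a[i], drop_bridge = i)
    six_side <- if (length(side) == 6L) side else setdiff(g$cells$cell_id, side)
    star %in% six_side
  }, logical(1))
  if (any(has_star)) cand <- cand[has_star]
  a <- pmin(out$cell_a[cand], out$cell_b[cand])
  b <- pmax(out$cell_a[cand], out$cell_b[cand])
  pick <- cand[order(out$round_created[cand], a, b)][1L]
  break_at(g, pick)
}

#' Simulation configuration for clone-level cyst development
#'
#' @param rounds Number of synchronous division rounds (default 5, the mouse
#'   program: each founder generates up to 32 cells).
#' @param fragmentation_schedule `"none"` (divisions only), `"eight_cell"`
#'   (a programmed break is applied to any fragment that reaches >= 7 cells
#'   after a round, whenever a six-cell cut exists), or `"quartet"` (a
#'   single fragmentation wave after round 5; see
#'   [quartet_fragmentation()]).
#' @param partial_round_policy Divider-choice policy for partial rounds; see
#'   [partial_cyst()].
#' @param oocyte_size Fragment size counted as producing one oocyte
#'   (default 6: each 6-cell derivative matures one oocyte plus five nurse
#'   cells).
#' @param seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rounds = 5L,
                       fragmentation_schedule = c("none", "eight_cell", "quartet"),
                       partial_round_policy = c("leaf_first", "random_subset"),
                       oocyte_size = 6L,
                       seed = NULL) {
  stopifnot(rounds >= 0)
  structure(list(rounds = as.integer(rounds),
                 fragmentation_schedule = match.arg(fragmentation_schedule),
                 partial_round_policy = match.arg(partial_round_policy),
                 oocyte_size = as.integer(oocyte_size),
                 seed = seed),
            class = "sim_config")
}

#' Quartet fragmentation of a 32-cell clone
#'
#' The clone-level programmed-fragmentation scheme: the three oldest
#' bridges (created in division rounds 1 and 2) are removed, splitting the
#' 32-cell canonical cyst into four 8-cell subtrees, and each subtree then
#' takes a programmed break at its microtubule-gap bridge. The result is
#' exactly four 6-cell cysts (each a future oocyte plus nurse cells) and
#' four 2-cell cysts.
#'
#' @param g32 The canonical 32-cell cyst (`canonical_cyst(5)` up to cell
#'   relabeling); structurally non-canonical input is rejected.
#' @return A `clonal_outcome`: list with `fragments` (list of
#'   `cyst_graph`s), `fragment_multiset` (named integer vector, size ->
#'   count), `oocyte_count`, `schedule_used`.
#' @export
#' @examples
#' out <- quartet_fragmentation(canonical_cyst(5))
#' out$fragment_multiset  # four 6-cell and four 2-cell cysts
quartet_fragmentation <- function(g32) {
  stopifnot(is_cyst_graph(g32))
  if (n_cells(g32) != 32L)
    stop("quartet fragmentation requires a 32-cell clone")
  rc <- sort(g32$bridges$round_created)
  if (!identical(rc, rep(1:5, times = c(1L, 2L, 4L, 8L, 16L))))
    stop("input is not a canonical 5-round cyst")
  old <- which(g32$bridges$round_created <= 2L)
  # peel off the four 8-cell subtrees by cutting the round-1/2 bridges
  parts <- list(g32)
  for (b in seq_along(old)) {
    parts <- do.call(c, lapply(parts, function(p) {
      i <- which(p$bridges$round_created <= 2L)
      if (length(i) == 0L) return(list(p))
      unclass(break_at(p, i[1L]))
    }))
  }
  if (!all(vapply(parts, n_cells, integer(1)) == 8L))
    stop("input is not a canonical 5-round cyst")
  frags <- do.call(c, lapply(parts, function(p) unclass(programmed_break(p))))
  clonal_outcome(frags, schedule = "quartet")
}

clonal_outcome <- function(fragments, schedule, oocyte_size = 6L) {
  sizes <- vapply(fragments, n_cells, integer(1))
  tab <- table(sizes)
  ms <- stats::setNames(as.integer(tab), names(tab))
  structure(list(fragments = fragments,
                 fragment_multiset = ms,
                 oocyte_count = sum(sizes == oocyte_size),
                 schedule_used = schedule),
            class = "clonal_outcome")
}

#' @export
print.clonal_outcome <- function(x, ...) {
  cat(sprintf("<clonal_outcome> schedule = %s\n", x$schedule_used))
  cat("fragment sizes: ",
      paste(sprintf("%s-cell x%d", names(x$fragment_multiset),
                    x$fragment_multiset), collapse = ", "), "\n")
  cat(sprintf("oocyte count: %d\n", x$oocyte_count))
  invisible(x)
}

#' Simulate a full clone: divisions plus a fragmentation schedule
#'
#' Runs `config$rounds` synchronous division rounds from a single founder.
#' Under schedule `"none"` the clone stays whole (32 cells after 5 rounds);
#' `"eight_cell"` applies a programmed break to every fragment of >= 7
#' cells after each round, provided the fragment has a six-cell cut;
#' `"quartet"` divides to 32 cells and then applies
#' [quartet_fragmentation()].
#'
#' @param config A [sim_config()].
#' @return A `clonal_outcome`.
#' @export
#' @examples
#' simulate_clone(sim_config(fragmentation_schedule = "quartet"))
simulate_clone <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  sched <- config$fragmentation_schedule
  if (sched == "quartet") {
    if (config$rounds != 5L)
      stop("the quartet schedule is defined for 5 division rounds")
    out <- quartet_fragmentation(canonical_cyst(5L))
    out$oocyte_count <- sum(vapply(out$fragments, n_cells, integer(1)) ==
                              config$oocyte_size)
    return(out)
  }
  frags <- list(cyst_founder())
  for (round in seq_len(config$rounds)) {
    frags <- lapply(frags, divide_round)
    if (sched == "eight_cell") {
      repeat {
        big <- which(vapply(frags, function(f) {
          n_cells(f) >= 7L && has_six_cut(f)
        }, logical(1)))
        if (length(big) == 0L) break
        i <- big[[1L]]
        frags <- c(frags[-i], unclass(programmed_break(frags[[i]])))
      }
    }
  }
  clonal_outcome(frags, schedule = sched, oocyte_size = config$oocyte_size)
}

has_six_cut <- function(g) {
  out <- enumerate_break_outcomes(g)
  any(out$size_small == 6L | out$size_large == 6L)
}
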