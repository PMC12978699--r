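#' @keywords internal
"_PACKAGE"

#' Create a founder germ cell
#'
#' The founder (a primordial germ cell, PGC) is the single cell from which a
#' germline cyst grows by consecutive synchronous, incomplete mitotic
#' divisions. It carries cell id 1 and generation 0.
#'
#' @return A `cyst_graph` with one cell, no bridges, and
#'   `rounds_completed = 0`.
#' @seealso [divide_round()], [canonical_cyst()]
#' @export
#' @examples
#' g <- cyst_founder()
#' n_cells(g)
cyst_founder <- function() {
  new_cyst_graph(
    cells = data.frame(cell_id = 1L, generation = 0L, parent = NA_integer_),
    bridges = data.frame(cell_a = integer(), cell_b = integer(),
                         round_created = integer()),
    rounds_completed = 0L
  )
}

new_cyst_graph <- function(cells, bridges, rounds_completed) {
  structure(
    list(cells = cells, bridges = bridges,
         rounds_completed = as.integer(rounds_completed)),
    class = "cyst_graph"
  )
}

#' Test or validate a cyst graph
#'
#' A valid cyst graph is a tree: connected, with exactly one bridge fewer
#' than cells, every bridge joining two distinct member cells, and cell ids
#' unique.
#'
#' @param g Object to test.
#' @return `is_cyst_graph()` returns `TRUE`/`FALSE`; `validate_cyst_graph()`
#'   returns `g` invisibly or throws an informative error.
#' @export
is_cyst_graph <- function(g) inherits(g, "cyst_graph")

#' @rdname is_cyst_graph
#' @export
validate_cyst_graph <- function(g) {
  stopifnot(is_cyst_graph(g))
  ids <- g$cells$cell_id
  if (anyDuplicated(ids)) stop("duplicate cell ids")
  if (nrow(g$bridges) != length(ids) - 1L)
    stop("not a tree: |bridges| != |cells| - 1")
  if (nrow(g$bridges) > 0L) {
    ends <- c(g$bridges$cell_a, g$bridges$cell_b)
    if (!all(ends %in% ids)) stop("bridge endpoint is not a member cell")
    if (any(g$bridges$cell_a == g$bridges$cell_b)) stop("self-bridge")
    key <- paste(pmin(g$bridges$cell_a, g$bridges$cell_b),
                 pmax(g$bridges$cell_a, g$bridges$cell_b))
    if (anyDuplicated(key)) stop("duplicate bridge")
  }
  comp <- reachable_cells(g, ids[1L])
  if (length(comp) != length(ids)) stop("graph is not connected")
  invisible(g)
}

#' Number of cells / bridges in a cyst
#'
#' @param g A `cyst_graph`.
#' @return An integer count.
#' @export
n_cells <- function(g) nrow(g$cells)

#' @rdname n_cells
#' @export
n_bridges <- function(g) nrow(g$bridges)

#' Cell ids of a cyst
#' @param g A `cyst_graph`.
#' @return Integer vector of cell ids, ascending.
#' @export
cyst_cells <- function(g) sort(g$cells$cell_id)

#' @export
print.cyst_graph <- function(x, ...) {
  cat(sprintf("<cyst_graph> %d cells, %d bridges, %d full division round%s\n",
              n_cells(x), n_bridges(x), x$rounds_completed,
              if (x$rounds_completed == 1L) "" else "s"))
  if (n_cells(x) <= 16L && n_bridges(x) > 0L) {
    cat("bridges (cell_a-cell_b @round): ",
        paste(sprintf("%d-%d@%d", x$bridges$cell_a, x$bridges$cell_b,
                      x$bridges$round_created), collapse = ", "), "\n")
  }
  invisible(x)
}

#' One round of synchronous incomplete division
#'
#' Each dividing cell spawns a daughter connected to it by a new
#' intercellular bridge; cytokinesis is incomplete so the bridge persists.
#' All pre-existing bridges of a divider remain attached to it (the
#' "retaining" daughter), which is what generates the maximally branched
#' canonical cyst topology. Daughter ids are assigned consecutively in
#' ascending order of their parents' ids.
#'
#' @param g A `cyst_graph`.
#' @param dividers Integer vector of cell ids that divide this round.
#'   Default `NULL` means every cell divides (a full synchronous round, which
#'   increments `rounds_completed`).
#' @return The enlarged `cyst_graph`.
#' @export
#' @examples
#' g <- divide_round(cyst_founder())  # 2-cell cyst
#' n_bridges(g)
divide_round <- function(g, dividers = NULL) {
  stopifnot(is_cyst_graph(g))
  ids <- g$cells$cell_id
  full <- is.null(dividers)
  if (full) dividers <- ids
  dividers <- as.integer(dividers)
  if (length(dividers) == 0L) stop("a division round needs at least one divider")
  if (anyDuplicated(dividers)) stop("duplicate dividers")
  if (!all(dividers %in% ids)) stop("dividers must be member cells")
  full <- full || setequal(dividers, ids)
  round <- g$rounds_completed + 1L

  dividers <- sort(dividers)
  daughters <- max(ids) + seq_along(dividers)
  g$cells <- rbind(g$cells, data.frame(
    cell_id = daughters, generation = round, parent = dividers))
  g$bridges <- rbind(g$bridges, data.frame(
    cell_a = dividers, cell_b = daughters, round_created = round))
  if (full) g$rounds_completed <- round
  g
}

#' The canonical (maximally branched) cyst
#'
#' Deterministic result of `r` full synchronous division rounds starting
#' from a founder, under the rule that all old bridges stay with one
#' daughter. For `r = 3` this is the 8-cell cyst with degree multiset
#' \{3,3,2,2,1,1,1,1\}; for `r = 5` the near-complete 32-cell mouse cyst.
#'
#' @param r Number of full division rounds (>= 0).
#' @return A `cyst_graph` with `2^r` cells.
#' @export
#' @examples
#' canonical_cyst(3)
canonical_cyst <- function(r) {
  stopifnot(length(r) == 1L, r >= 0)
  g <- cyst_founder()
  for (i in seq_len(r)) g <- divide_round(g)
  g
}

#' Cysts of intermediate size via a partial division round
#'
#' Cyst sizes between powers of two (such as the 7-, 9- and 10-cell cysts
#' observed in lineage-labeled ovaries) are modeled as a canonical cyst of
#' `floor(log2(n_cells))` rounds caught partway through its next round:
#' `n_cells - 2^r` cells have already divided. Which cells lead the division
#' wave is not known, so two policies are provided.
#'
#' @param n_cells Target cell count (>= 2).
#' @param policy `"leaf_first"`: the lowest-degree cells divide first, ties
#'   broken by lowest cell id (deterministic). `"random_subset"`: a seeded
#'   uniform choice of dividers.
#' @param seed Optional integer seed, used only by `"random_subset"`.
#' @return A `cyst_graph` with exactly `n_cells` cells.
#' @export
#' @examples
#' partial_cyst(7)           # 4-cell base, three cells mid-division
#' partial_cyst(10)          # 8-cell base, two cells mid-division
partial_cyst <- function(n_cells, policy = c("leaf_first", "random_subset"),
                         seed = NULL) {
  policy <- match.arg(policy)
  stopifnot(length(n_cells) == 1L, n_cells >= 2)
  n_cells <- as.integer(n_cells)
  r <- floor(log2(n_cells))
  g <- canonical_cyst(r)
  extra <- n_cells - 2L^r
  if (extra == 0L) return(g)
  dividers <- switch(policy,
    leaf_first = {
      deg <- cyst_degrees(g)
      ord <- order(deg, g$cells$cell_id)
      g$cells$cell_id[ord][seq_len(extra)]
    },
    random_subset = {
      if (!is.null(seed)) withr::local_seed(seed)
      sample(g$cells$cell_id, extra)
    })
  divide_round(g, dividers)
}

#' Bridge degrees of cyst cells
#'
#' @param g A `cyst_graph`.
#' @param cell A single cell id (for `degree_of()`).
#' @return `cyst_degrees()`: integer vector of bridge counts named by cell
#'   id, in the order of `g$cells`. `degree_of()`: a single count.
#' @export
cyst_degrees <- function(g) {
  deg <- tabulate(match(c(g$bridges$cell_a, g$bridges$cell_b),
                        g$cells$cell_id),
                  nbins = nrow(g$cells))
  names(deg) <- g$cells$cell_id
  deg
}

#' @rdname cyst_degrees
#' @export
degree_of <- function(g, cell) {
  if (!cell %in% g$cells$cell_id) stop("cell not in graph")
  unname(cyst_degrees(g)[as.character(cell)])
}

#' Most-branched cell of a cyst
#'
#' The cell connected by the most intercellular bridges; ties are broken by
#' the smallest cell id. In the fusome model this is the pro-oocyte: the
#' fusome-enriched, multi-bridge cell.
#'
#' @param g A `cyst_graph`.
#' @return A single cell id.
#' @export
max_degree_cell <- function(g) {
  deg <- cyst_degrees(g)
  ids <- g$cells$cell_id
  cand <- ids[deg == max(deg)]
  min(cand)
}

# Cells reachable from `start`, optionally ignoring bridge row `drop_bridge`.
# Plain integer BFS: cyst graphs have at most a few dozen cells and this is
# on the hot path of the Monte-Carlo breakage simulations.
reachable_cells <- function(g, start, drop_bridge = 0L) {
  ids <- g$cells$cell_id
  n <- length(ids)
  keep <- setdiff(seq_len(nrow(g$bridges)), drop_bridge)
  a <- match(g$bridges$cell_a[keep], ids)
  b <- match(g$bridges$cell_b[keep], ids)
  seen <- logical(n)
  queue <- match(start, ids)
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- c(b[a == v], a[b == v])
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  ids[seen]
}

# Extract the induced sub-cyst on a set of member cells (must be connected).
induced_subcyst <- function(g, keep_cells) {
  cells <- g$cells[g$cells$cell_id %in% keep_cells, , drop = FALSE]
  cells$parent[!(cells$parent %in% keep_cells)] <- NA_integer_
  bridges <- g$bridges[g$bridges$cell_a %in% keep_cells &
                       g$bridges$cell_b %in% keep_cells, , drop = FALSE]
  rownames(cells) <- rownames(bridges) <- NULL
  new_cyst_graph(cells, bridges, g$rounds_completed)
}

# Locate the row index of a bridge given as c(cell_a, cell_b) (either order).
bridge_index <- function(g, bridge) {
  stopifnot(length(bridge) == 2L)
  i <- which((g$bridges$cell_a == bridge[1L] & g$bridges$cell_b == bridge[2L]) |
             (g$bridges$cell_a == bridge[2L] & g$bridges$cell_b == bridge[1L]))
  if (length(i) != 1L) stop("bridge not in graph")
  i
}

#' Convert a cyst to an igraph object
#'
#' Vertices carry `generation`; edges carry `round_created`. Useful for
#' plotting and for cross-checking connectivity with standard graph
#' routines.
#'
#' @param g A `cyst_graph`.
#' @return An undirected [igraph::graph] object.
#' @export
as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(g$bridges$cell_a),
                   to = as.character(g$bridges$cell_b),
                   round_created = g$bridges$round_created),
    directed = FALSE,
    vertices = data.frame(name = as.character(g$cells$cell_id),
                          generation = g$cells$generation))
  ig
}

#' Export and re-import the bridge network as a tab-separated edge list
#'
#' One bridge per line: `cell_a<TAB>cell_b<TAB>round_created`. The edge list
#' is loss-free for the bridge network; on re-import the lineage (parent
#' assignments) is recovered by rooting the tree at the smallest cell id and
#' reading each cell's parental bridge as the bridge on its path to the
#' root.
#'
#' @param g A `cyst_graph`.
#' @param path Optional file path. If `NULL`, the lines are returned.
#' @return `export_edge_list()`: the lines (invisibly when written to
#'   `path`); `read_edge_list()`: a `cyst_graph`.
#' @export
export_edge_list <- function(g, path = NULL) {
  lines <- sprintf("%d\t%d\t%d", g$bridges$cell_a, g$bridges$cell_b,
                   g$bridges$round_created)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname export_edge_list
#' @param lines Character vector of edge-list lines (alternative to `path`).
#' @export
read_edge_list <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path)
  m <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.integer))
  bridges <- data.frame(cell_a = m[, 1L], cell_b = m[, 2L],
                        round_created = m[, 3L])
  ids <- sort(unique(c(bridges$cell_a, bridges$cell_b)))
  root <- min(ids)
  # recover parents by BFS from the root
  parent <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  gen <- stats::setNames(rep(0L, length(ids)), ids)
  queue <- root
  seen <- root
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    hit <- bridges$cell_a == v | bridges$cell_b == v
    nbr <- setdiff(c(bridges$cell_a[hit], bridges$cell_b[hit]), seen)
    for (w in nbr) {
      parent[as.character(w)] <- v
      i <- which(hit & (bridges$cell_a == w | bridges$cell_b == w))[1L]
      gen[as.character(w)] <- bridges$round_created[i]
    }
    seen <- c(seen, nbr)
    queue <- c(queue, nbr)
  }
  g <- new_cyst_graph(
    cells = data.frame(cell_id = ids, generation = unname(gen[as.character(ids)]),
                       parent = unname(parent[as.character(ids)])),
    bridges = bridges,
    rounds_completed = if (nrow(bridges)) max(bridges$round_created) else 0L)
  validate_cyst_graph(g)
  g
}

#' Export the division lineage as a Newick string
#'
#' The cyst tree rooted at the founder, with cell ids as labels and each
#' branch length equal to the division round that created the cell, so the
#' parent-to-daughter history is fully recoverable.
#'
#' @param g A `cyst_graph`.
#' @return A single Newick string (terminated by `;`).
#' @export
export_newick <- function(g) {
  root <- g$cells$cell_id[is.na(g$cells$parent)]
  if (length(root) != 1L) root <- min(g$cells$cell_id)
  rec <- function(v) {
    kids <- sort(g$cells$cell_id[!is.na(g$cells$parent) & g$cells$parent == v])
    gen <- g$cells$generation[g$cells$cell_id == v]
    lab <- sprintf("%d:%d", v, gen)
    if (length(kids) == 0L) return(lab)
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")", lab)
  }
  paste0(rec(root), ";")
}

#' Serialize a cyst graph to and from JSON
#'
#' @param g A `cyst_graph`.
#' @param path Optional file path for the JSON text.
#' @return `cyst_to_json()`: a JSON string (invisibly when written);
#'   `cyst_from_json()`: a `cyst_graph`.
#' @export
cyst_to_json <- function(g, path = NULL) {
  txt <- jsonlite::toJSON(list(cells = g$cells, bridges = g$bridges,
                               rounds_completed = g$rounds_completed),
                          dataframe = "columns", na = "null", auto_unbox = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname cyst_to_json
#' @param txt A JSON string (alternative to `path`).
#' @export
cyst_from_json <- function(path = NULL, txt = NULL) {
  if (is.null(txt)) txt <- paste(readLines(path), collapse = "\n")
  x <- jsonlite::fromJSON(txt)
  cells <- as.data.frame(x$cells)
  cells$parent <- as.integer(cells$parent)
  bridges <- as.data.frame(x$bridges)
  if (nrow(bridges) == 0L)
    bridges <- data.frame(cell_a = integer(), cell_b = integer(),
                          round_created = integer())
  g <- new_cyst_graph(cells, bridges, x$rounds_completed)
  validate_cyst_graph(g)
  g
}
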