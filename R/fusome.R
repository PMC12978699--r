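#' Parameters of the fusome-inheritance model
#'
#' The fusome (the Golgi/ER-rich organelle spanning intercellular bridges)
#' is modeled as a per-cell scalar volume. At each division the parent's
#' volume splits `f : (1 - f)`, with the bridge-retaining daughter (the one
#' keeping all old bridges) receiving the fraction `f`; each daughter also
#' gains `delta / 2` of freshly deposited material, and each daughter's
#' volume is multiplied by independent lognormal noise.
#'
#' @param V0 Founder fusome volume in cubic micrometers (default 1; volumes
#'   scale linearly in `V0`).
#' @param f Retention fraction in (0, 1) to the bridge-retaining daughter.
#'   Default 0.7: a reproducible ~2.3:1 sister asymmetry, matching the
#'   consistent inequality of sister granule volumes seen in 2-cell cysts.
#' @param delta New fusome material deposited per division (same units as
#'   `V0`), split equally between the daughters. Default 0.2: fresh
#'   material appears at each cleavage furrow but the inherited pool
#'   dominates.
#' @param sigma Standard deviation of the multiplicative lognormal noise
#'   (dimensionless; 0 = deterministic). Default 0.25, a realistic
#'   cell-to-cell scatter for organelle volume quantifications.
#' @return A `fusome_params` list.
#' @export
fusome_params <- function(V0 = 1, f = 0.7, delta = 0.2, sigma = 0.25) {
  stopifnot(V0 > 0, f > 0, f < 1, delta >= 0, sigma >= 0)
  structure(list(V0 = V0, f = f, delta = delta, sigma = sigma),
            class = "fusome_params")
}

#' Simulate asymmetric fusome inheritance over a cyst lineage
#'
#' Replays the division history recorded in a `cyst_graph` (each non-founder
#' cell's parent and creation round) and propagates fusome volumes under
#' the asymmetric-inheritance rule of [fusome_params()]. With `sigma = 0`
#' and `delta = 0` the volume of each cell is `V0` times the product of `f`
#' or `(1 - f)` factors along its retention path, so for `f > 0.5` the
#' most-branched cell (the pro-oocyte) always holds the most fusome.
#'
#' @param g A `cyst_graph` built by division (cells carry `parent` and
#'   `generation`).
#' @param params A [fusome_params()].
#' @param seed Optional integer seed (used when `sigma > 0`).
#' @return A `fusome_state`: named numeric vector of volumes, names = cell
#'   ids, in cell-id order.
#' @export
#' @examples
#' simulate_fusome(canonical_cyst(3), fusome_params(f = 0.7, delta = 0, sigma = 0))
simulate_fusome <- function(g, params = fusome_params(), seed = NULL) {
  stopifnot(is_cyst_graph(g), inherits(params, "fusome_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  if (any(!is.na(g$cells$parent) & !(g$cells$parent %in% g$cells$cell_id)))
    stop("lineage incomplete: a cell's parent is missing from the graph")
  vol <- stats::setNames(rep(NA_real_, nrow(g$cells)), g$cells$cell_id)
  root <- g$cells$cell_id[is.na(g$cells$parent)]
  stopifnot(length(root) == 1L)
  vol[as.character(root)] <- params$V0
  rounds <- sort(unique(g$cells$generation[!is.na(g$cells$parent)]))
  for (round in rounds) {
    born <- g$cells[!is.na(g$cells$parent) & g$cells$generation == round, ,
                    drop = FALSE]
    for (i in seq_len(nrow(born))) {
      p <- as.character(born$parent[i]); d <- as.character(born$cell_id[i])
      V <- vol[[p]]
      v_retain <- params$f * V + params$delta / 2
      v_new <- (1 - params$f) * V + params$delta / 2
      if (params$sigma > 0) {
        v_retain <- v_retain * stats::rlnorm(1, 0, params$sigma)
        v_new <- v_new * stats::rlnorm(1, 0, params$sigma)
      }
      vol[[p]] <- v_retain
      vol[[d]] <- v_new
    }
  }
  structure(vol[order(as.integer(names(vol)))], class = "fusome_state")
}

#' Sister-cell asymmetry index
#'
#' `|v1 - v2| / (v1 + v2)`: 0 for equal sisters, approaching 1 for complete
#' asymmetry.
#'
#' @param v1,v2 Non-negative volumes, not both zero (vectorized).
#' @return Values in \[0, 1\].
#' @export
#' @examples
#' asymmetry_index(7, 3)  # 0.4
asymmetry_index <- function(v1, v2) {
  if (any(v1 + v2 <= 0)) stop("asymmetry index undefined when both volumes are zero")
  abs(v1 - v2) / (v1 + v2)
}

#' Fusome enrichment versus bridge count
#'
#' Tabulates, for each cell, its bridge count (ring-canal number) and fusome
#' volume, and reports the Spearman rank correlation between the two (ties
#' handled by mid-ranks), together with whether the cell holding the most
#' fusome is also the most-branched cell. When either variable is constant
#' the correlation is degenerate and reported as 0 with `degenerate = TRUE`.
#'
#' @param g A `cyst_graph`.
#' @param state A `fusome_state` covering all cells of `g`.
#' @return A list: `table` (data frame `cell`, `degree`, `fusome_volume`),
#'   `rank_correlation`, `degenerate`, `max_fusome_is_max_degree`.
#' @export
enrichment_report <- function(g, state) {
  ids <- as.character(g$cells$cell_id)
  if (!all(ids %in% names(state)))
    stop("fusome state does not cover all cells")
  deg <- cyst_degrees(g)
  tab <- data.frame(cell = g$cells$cell_id,
                    degree = unname(deg[ids]),
                    fusome_volume = unname(state[ids]))
  tab <- tab[order(tab$cell), , drop = FALSE]
  rownames(tab) <- NULL
  degenerate <- stats::sd(tab$degree) == 0 || stats::sd(tab$fusome_volume) == 0
  rho <- if (degenerate) 0 else
    stats::cor(tab$degree, tab$fusome_volume, method = "spearman")
  top_fusome <- tab$cell[which.max(tab$fusome_volume)]
  list(table = tab,
       rank_correlation = rho,
       degenerate = degenerate,
       max_fusome_is_max_degree = top_fusome == max_degree_cell(g))
}
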