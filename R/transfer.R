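#' Parameters of the nurse-cell transfer model
#'
#' During meiosis, cyst cells are progressively activated as nurse cells:
#' each activated cell transfers most of its cytoplasm one bridge-hop
#' toward the oocyte and then dies, leaving a small remnant. Activation is
#' modeled as a Poisson clock; transfer is hop-wise along the shrinking
#' tree, so losses compound with distance from the oocyte.
#'
#' @param epsilon Per-transfer efficiency in \[0, 1\]: fraction of the
#'   donor's current content passed to its neighbor; the rest is discarded
#'   as the nurse-cell remnant. Default 0.9 ("most of its cytoplasm").
#' @param rate Activation rate in events per day. Default 0.5: on average
#'   one cell becomes a nurse cell every 2 days.
#' @param order_policy `"leaf_first"`: current leaves of the shrinking tree
#'   activate first, lowest bridge count then lowest id; `"random"`:
#'   uniform choice among current leaves (internal cells cannot donate
#'   without disconnecting the cyst).
#' @param c0 Initial organelle content per cell (arbitrary units).
#' @return A `transfer_params` list.
#' @export
transfer_params <- function(epsilon = 0.9, rate = 0.5,
                            order_policy = c("leaf_first", "random"),
                            c0 = 1) {
  stopifnot(epsilon >= 0, epsilon <= 1, rate > 0, c0 > 0)
  structure(list(epsilon = epsilon, rate = rate,
                 order_policy = match.arg(order_policy), c0 = c0),
            class = "transfer_params")
}

#' Simulate nurse-cell activation and cytoplasmic transfer
#'
#' The oocyte is the most-branched cell of the fragment (ties to the
#' smallest id). Activation times are drawn from an exponential inter-event
#' clock at `rate`; at each event a donor leaf is chosen by `order_policy`,
#' sends `epsilon` times its current content to its unique tree neighbor
#' (one hop along the path toward the oocyte), and is removed. The process
#' ends when only the oocyte remains.
#'
#' @param fragment A `cyst_graph` with at least 2 cells.
#' @param params A [transfer_params()].
#' @param seed Optional integer seed.
#' @return A `transfer_timeline`: list with `events` (data frame
#'   `time_days`, `donor`, `recipient`, `amount`, `remnant`), `oocyte`,
#'   `final_content` (oocyte content), `fold_enrichment`
#'   (`final_content / c0`), `total_remnant`.
#' @export
#' @examples
#' frag <- programmed_break(canonical_cyst(3))[[2]]  # the 6-cell derivative
#' simulate_transfer(frag, transfer_params(epsilon = 1), seed = 1)$fold_enrichment
simulate_transfer <- function(fragment, params = transfer_params(),
                              seed = NULL) {
  stopifnot(is_cyst_graph(fragment), n_cells(fragment) >= 2L,
            inherits(params, "transfer_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  oocyte <- max_degree_cell(fragment)
  g <- fragment
  content <- stats::setNames(rep(params$c0, n_cells(g)), g$cells$cell_id)
  events <- vector("list", n_cells(g) - 1L)
  t_now <- 0
  for (step in seq_len(n_cells(fragment) - 1L)) {
    t_now <- t_now + stats::rexp(1, rate = params$rate)
    deg <- cyst_degrees(g)
    leaves <- g$cells$cell_id[deg == 1L]
    leaves <- setdiff(leaves, oocyte)
    if (length(leaves) == 0L) leaves <- setdiff(g$cells$cell_id, oocyte)
    donor <- switch(params$order_policy,
      leaf_first = {
        ord <- order(unname(deg[as.character(leaves)]), leaves)
        leaves[ord][1L]
      },
      random = leaves[sample.int(length(leaves), 1L)])
    i <- which(g$bridges$cell_a == donor | g$bridges$cell_b == donor)[1L]
    recipient <- setdiff(c(g$bridges$cell_a[i], g$bridges$cell_b[i]), donor)
    amount <- params$epsilon * content[[as.character(donor)]]
    remnant <- content[[as.character(donor)]] - amount
    content[[as.character(recipient)]] <-
      content[[as.character(recipient)]] + amount
    events[[step]] <- data.frame(time_days = t_now, donor = donor,
                                 recipient = recipient, amount = amount,
                                 remnant = remnant)
    content <- content[names(content) != as.character(donor)]
    g <- induced_subcyst(g, setdiff(g$cells$cell_id, donor))
  }
  ev <- do.call(rbind, events)
  structure(list(events = ev, oocyte = oocyte,
                 final_content = unname(content[[as.character(oocyte)]]),
                 fold_enrichment = unname(content[[as.character(oocyte)]]) /
                   params$c0,
                 total_remnant = sum(ev$remnant)),
            class = "transfer_timeline")
}

#' @export
print.transfer_timeline <- function(x, ...) {
  cat(sprintf("<transfer_timeline> %d transfers into oocyte (cell %d)\n",
              nrow(x$events), x$oocyte))
  cat(sprintf("final content %.3f (%.2f-fold enrichment), remnant %.3f\n",
              x$final_content, x$fold_enrichment, x$total_remnant))
  invisible(x)
}

#' Expected time for a cyst fragment to break down completely
#'
#' With one activation on average every `1 / rate` days, dissolving an
#' n-cell fragment down to its single surviving oocyte takes `n - 1`
#' activations, so the expected breakdown time is `(n - 1) / rate` days.
#'
#' @param n_cells Fragment size (>= 2).
#' @param rate Activation rate in events per day.
#' @return Expected breakdown time in days.
#' @export
#' @examples
#' expected_breakdown_time(6, 0.5)  # 10 days
expected_breakdown_time <- function(n_cells, rate = 0.5) {
  stopifnot(n_cells >= 2, rate > 0)
  (n_cells - 1) / rate
}
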