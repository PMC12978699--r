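#' Generate a synthetic per-cell measurement table
#'
#' Emulates the structure of lineage-labeled cyst quantifications: one row
#' per cell with bridge count, fusome volume, an apical-polarity (Pard3)
#' stained area that tracks the fusome, and a nucleus diameter. Topologies
#' come from [partial_cyst()] and volumes from [simulate_fusome()], so the
#' statistical couplings (sister asymmetry, fusome enrichment in
#' multi-bridge cells) are inherited from the generative models rather than
#' imposed on the table.
#'
#' @param n_cysts Number of cysts.
#' @param sizes Integer vector of cyst sizes, recycled to `n_cysts`
#'   (default 8).
#' @param params A [fusome_params()].
#' @param stage_label Character label column (recycled), e.g. an embryonic
#'   day.
#' @param nucleus_mean Mean nucleus diameter in micrometers (default 9, a
#'   typical early germ-cell nucleus).
#' @param noise_sd Lognormal spread of nucleus diameter and Pard3 area.
#' @param seed Optional integer seed; a fixed seed reproduces the table
#'   exactly.
#' @return A `measurement_table` data frame: `cyst_id`, `cell_id`,
#'   `stage_label`, `n_bridges`, `fusome_volume_um3`, `pard3_area_um2`,
#'   `nucleus_diameter_um`.
#' @export
#' @examples
#' head(make_measurement_table(2, sizes = 8, seed = 1))
make_measurement_table <- function(n_cysts, sizes = 8L,
                                   params = fusome_params(),
                                   stage_label = "E12.5",
                                   nucleus_mean = 9, noise_sd = 0.1,
                                   seed = NULL) {
  stopifnot(n_cysts >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  sizes <- rep_len(as.integer(sizes), n_cysts)
  stage_label <- rep_len(stage_label, n_cysts)
  rows <- lapply(seq_len(n_cysts), function(ci) {
    g <- partial_cyst(sizes[ci])
    st <- simulate_fusome(g, params)
    deg <- cyst_degrees(g)
    ids <- sort(g$cells$cell_id)
    vol <- unname(st[as.character(ids)])
    # Pard3 mirrors the fusome: stained area scales like volume^(2/3)
    pard3 <- 5 * vol^(2 / 3) * stats::rlnorm(length(ids), 0, noise_sd)
    nuc <- nucleus_mean * stats::rlnorm(length(ids), 0, noise_sd)
    data.frame(cyst_id = ci, cell_id = ids, stage_label = stage_label[ci],
               n_bridges = unname(deg[as.character(ids)]),
               fusome_volume_um3 = vol, pard3_area_um2 = pard3,
               nucleus_diameter_um = nuc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Generate a synthetic microtubule-gap dataset
#'
#' One record per cyst: a modeled topology of the requested size and the
#' single bridge lacking a stable-microtubule connection (the predicted
#' break site). Under `truth = "programmed"` the gap is placed at a bridge
#' whose removal releases a 6-cell fragment with probability `1 - eta`
#' (falling back to a uniform choice among the other bridges, or among all
#' bridges when the topology has no 6-yielding cut); under
#' `truth = "random"` the gap is uniform over all bridges.
#' `six_predicted` is always derived from the graph by [fragment_sizes()],
#' never stored independently.
#'
#' @param size_mix Named integer vector, cyst size -> count. Default is the
#'   published 15-cyst composition: 3 seven-, 8 eight-, 1 nine- and 3
#'   ten-cell cysts.
#' @param truth `"programmed"` or `"random"`.
#' @param eta Miscall rate in \[0, 1\] for programmed truth.
#' @param topology_policy Passed to [partial_cyst()].
#' @param seed Optional integer seed.
#' @return An `mt_gap_dataset`: list of records, each with `cyst_id`,
#'   `cyst_size`, `graph` (`cyst_graph`), `gap_edge` (length-2 cell ids),
#'   `six_predicted`.
#' @export
#' @examples
#' ds <- make_mt_gap_dataset(truth = "programmed", seed = 1)
#' sum(vapply(ds, `[[`, logical(1), "six_predicted"))
make_mt_gap_dataset <- function(size_mix = c(`7` = 3L, `8` = 8L, `9` = 1L,
                                             `10` = 3L),
                                truth = c("programmed", "random"),
                                eta = 0, topology_policy = "leaf_first",
                                seed = NULL) {
  truth <- match.arg(truth)
  stopifnot(eta >= 0, eta <= 1, !is.null(names(size_mix)))
  if (!is.null(seed)) withr::local_seed(seed)
  sizes <- rep(as.integer(names(size_mix)), times = size_mix)
  # the leaf_first topology is deterministic per size: build each once
  memo <- topology_policy == "leaf_first"
  if (memo) {
    graphs <- lapply(unique(sizes), partial_cyst, policy = topology_policy)
    names(graphs) <- unique(sizes)
    outcomes <- lapply(graphs, enumerate_break_outcomes)
  }
  records <- lapply(seq_along(sizes), function(ci) {
    if (memo) {
      g <- graphs[[as.character(sizes[ci])]]
      out <- outcomes[[as.character(sizes[ci])]]
    } else {
      g <- partial_cyst(sizes[ci], policy = topology_policy)
      out <- enumerate_break_outcomes(g)
    }
    six_idx <- which(out$size_small == 6L | out$size_large == 6L)
    idx <- if (truth == "random" || length(six_idx) == 0L) {
      sample.int(nrow(out), 1L)
    } else if (stats::runif(1) >= eta) {
      six_idx[sample.int(length(six_idx), 1L)]
    } else {
      other <- setdiff(seq_len(nrow(out)), six_idx)
      if (length(other) == 0L) six_idx[sample.int(length(six_idx), 1L)]
      else other[sample.int(length(other), 1L)]
    }
    gap <- c(out$cell_a[idx], out$cell_b[idx])
    list(cyst_id = ci, cyst_size = sizes[ci], graph = g, gap_edge = gap,
         six_predicted = any(fragment_sizes(g, gap) == 6L))
  })
  structure(records, class = "mt_gap_dataset")
}

#' Collapse an mt-gap dataset to a breakage sample
#'
#' @param ds An `mt_gap_dataset`.
#' @return A [breakage_sample()] with one record per cyst.
#' @export
as_breakage_sample <- function(ds) {
  stopifnot(inherits(ds, "mt_gap_dataset"))
  breakage_sample(vapply(ds, `[[`, integer(1), "cyst_size"),
                  vapply(ds, `[[`, logical(1), "six_predicted"))
}

#' Voxelize spherical granules onto a labeled 3-D grid
#'
#' Builds the synthetic oracle for volume quantification: each
#' non-overlapping sphere is rasterized by labeling every voxel whose
#' center lies inside it. Volume measurement is then voxel counting times
#' the voxel volume, the generic analogue of surface-rendering volume
#' readouts.
#'
#' @param spheres Data frame with columns `x`, `y`, `z` (center, in
#'   micrometers) and `radius` (micrometers); spheres must not overlap.
#' @param voxel_size Voxel edge length in micrometers.
#' @return A `voxel_volume`: list with `labels` (3-D integer array),
#'   `voxel_size`, `spheres`, `origin` (coordinates of the first voxel
#'   center).
#' @export
#' @examples
#' vv <- voxelize_granules(data.frame(x = 0, y = 0, z = 0, radius = 2),
#'                         voxel_size = 0.5)
#' measure_volume(vv, 1)
voxelize_granules <- function(spheres, voxel_size) {
  stopifnot(is.data.frame(spheres), nrow(spheres) >= 0, voxel_size > 0,
            all(c("x", "y", "z", "radius") %in% names(spheres)),
            all(spheres$radius > 0))
  if (nrow(spheres) >= 2L) {
    for (i in seq_len(nrow(spheres) - 1L)) for (j in (i + 1L):nrow(spheres)) {
      d <- sqrt(sum((spheres[i, c("x", "y", "z")] -
                     spheres[j, c("x", "y", "z")])^2))
      if (d < spheres$radius[i] + spheres$radius[j])
        stop("overlapping spheres")
    }
  }
  if (nrow(spheres) == 0L) {
    return(structure(list(labels = array(0L, c(1L, 1L, 1L)),
                          voxel_size = voxel_size, spheres = spheres,
                          origin = c(0, 0, 0)),
                     class = "voxel_volume"))
  }
  lo <- vapply(c("x", "y", "z"), function(a) min(spheres[[a]] - spheres$radius),
               numeric(1)) - voxel_size
  hi <- vapply(c("x", "y", "z"), function(a) max(spheres[[a]] + spheres$radius),
               numeric(1)) + voxel_size
  # voxel centers sit on a world-anchored lattice (integer multiples of the
  # voxel size) so the rasterization of a fixed scene is independent of the
  # bounding box and refines consistently as voxel_size shrinks
  centers <- lapply(1:3, function(a)
    seq(floor(lo[a] / voxel_size), ceiling(hi[a] / voxel_size)) * voxel_size)
  dims <- lengths(centers)
  labels <- array(0L, dims)
  for (s in seq_len(nrow(spheres))) {
    dx2 <- (centers[[1]] - spheres$x[s])^2
    dy2 <- (centers[[2]] - spheres$y[s])^2
    dz2 <- (centers[[3]] - spheres$z[s])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= spheres$radius[s]^2
    labels[inside] <- s
  }
  structure(list(labels = labels, voxel_size = voxel_size, spheres = spheres,
                 origin = vapply(centers, `[`, numeric(1), 1L)),
            class = "voxel_volume")
}

#' @rdname voxelize_granules
#' @param vv A `voxel_volume`.
#' @param label Integer label to measure.
#' @return `measure_volume()`: the measured volume in cubic micrometers
#'   (voxel count times `voxel_size^3`).
#' @export
measure_volume <- function(vv, label) {
  stopifnot(inherits(vv, "voxel_volume"))
  sum(vv$labels == label) * vv$voxel_size^3
}

#' Write a measurement table or transfer timeline to CSV
#'
#' Plain comma-separated UTF-8 with a header row and `.` decimal separator;
#' a sidecar JSON (same path with `.json` appended) records the generator
#' seed and parameters when supplied.
#'
#' @param x A data frame (e.g. a `measurement_table` or the `events` of a
#'   `transfer_timeline`).
#' @param path Output CSV path.
#' @param meta Optional named list written to the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_cystkit_csv <- function(x, path, meta = NULL) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(path)
}
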