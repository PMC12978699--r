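#!/usr/bin/env Rscript
# Nurse-cell activation and hop-wise cytoplasmic transfer into the oocyte.
#
# Finding: a 6-cell derivative funnels its contents into the most-branched
# cell; at per-hop efficiency 0.9 the oocyte ends ~5-fold enriched (losses
# compound per hop, so the fold stays below the 6-fold conservation bound),
# and breakdown of a 6-cell cyst at one activation per 2 days takes 10 days
# in expectation.

suppressPackageStartupMessages(library(cystkit))
dir.create("results", showWarnings = FALSE)

frags <- programmed_break(canonical_cyst(3))
six <- frags[[which(vapply(frags, n_cells, integer(1)) == 6L)]]

tl <- simulate_transfer(six, transfer_params(epsilon = 0.9), seed = 42)
print(tl)
write_cystkit_csv(tl$events, "results/transfer_timeline.csv",
                  meta = list(seed = 42, epsilon = 0.9, rate = 0.5))

folds <- vapply(seq(0.5, 1, by = 0.1), function(e)
  simulate_transfer(six, transfer_params(epsilon = e), seed = 42)$fold_enrichment,
  numeric(1))
cat("fold enrichment vs per-hop efficiency:\n")
print(data.frame(epsilon = seq(0.5, 1, by = 0.1), fold = folds),
      row.names = FALSE)

set.seed(7)
mc_times <- vapply(1:2000, function(i) {
  ev <- simulate_transfer(six, transfer_params(epsilon = 0.9))$events
  ev$time_days[nrow(ev)]
}, numeric(1))
cat(sprintf("breakdown of a 6-cell cyst: closed form %.1f d, Monte-Carlo %.2f d\n",
            expected_breakdown_time(6, 0.5), mean(mc_times)))

jsonlite::write_json(list(fold_at_eps_0.9 = tl$fold_enrichment,
                          fold_by_epsilon = data.frame(
                            epsilon = seq(0.5, 1, by = 0.1), fold = folds),
                          expected_breakdown_days = expected_breakdown_time(6, 0.5),
                          mc_mean_breakdown_days = mean(mc_times)),
                     "results/transfer_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("written: results/transfer_timeline.csv, results/transfer_summary.json\n")
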