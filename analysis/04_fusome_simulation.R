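#!/usr/bin/env Rscript
# Asymmetric fusome inheritance across cyst divisions.
#
# Finding: with retention fraction f = 0.7 the founder's lineage
# concentrates fusome in the multi-bridge cells: in the noise-free 8-cell
# cyst the pro-oocyte (degree-3 founder) holds 0.343 of the initial volume
# versus 0.027 in the most peripheral cell, and bridge count rank-correlates
# with fusome volume even under lognormal measurement noise.

suppressPackageStartupMessages(library(cystkit))
dir.create("results", showWarnings = FALSE)

g8 <- canonical_cyst(3)
clean <- simulate_fusome(g8, fusome_params(f = 0.7, delta = 0, sigma = 0))
rep_clean <- enrichment_report(g8, clean)
print(rep_clean$table)
cat(sprintf("noise-free rank correlation (degree vs volume): %.3f\n",
            rep_clean$rank_correlation))

# repeatedly simulate with measurement noise and summarize the coupling
set.seed(20260929)
noisy <- t(vapply(1:200, function(i) {
  st <- simulate_fusome(g8, fusome_params(f = 0.7, delta = 0.2, sigma = 0.25))
  rep_i <- enrichment_report(g8, st)
  c(rho = rep_i$rank_correlation, top = as.numeric(rep_i$max_fusome_is_max_degree))
}, numeric(2)))
cat(sprintf("noisy replicates: mean rho = %.3f, pro-oocyte holds max fusome in %.0f%%\n",
            mean(noisy[, "rho"]), 100 * mean(noisy[, "top"])))

# 2-cell sister asymmetry, as quantified in lineage-labeled pairs
tab2 <- make_measurement_table(16, sizes = 2,
                               params = fusome_params(f = 0.7, sigma = 0.25),
                               seed = 11)
asym <- vapply(split(tab2$fusome_volume_um3, tab2$cyst_id),
               function(v) asymmetry_index(v[1], v[2]), numeric(1))
cat(sprintf("mean sister asymmetry index over 16 two-cell cysts: %.3f\n",
            mean(asym)))

write_cystkit_csv(rep_clean$table, "results/fusome_enrichment_8cell.csv")
jsonlite::write_json(list(noise_free_rho = rep_clean$rank_correlation,
                          noisy_mean_rho = mean(noisy[, "rho"]),
                          noisy_top_fraction = mean(noisy[, "top"]),
                          mean_sister_asymmetry = mean(asym)),
                     "results/fusome_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("written: results/fusome_enrichment_8cell.csv, results/fusome_summary.json\n")
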