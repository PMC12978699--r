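#!/usr/bin/env Rscript
# Operating characteristics of the pooled binomial breakage test.
#
# Finding: with programmed gap placement and no miscalls, samples of 15
# 8-cell cysts reject the random-breakage null at alpha = 1e-4 in every
# replicate; under random gap placement the discrete test is conservative
# (rejection rate below the nominal 5%). Miscall rates up to ~20% leave the
# test near-fully powered.

suppressPackageStartupMessages(library(cystkit))
dir.create("results", showWarnings = FALSE)

reps <- 1000L
rows <- do.call(rbind, c(
  lapply(c(0, 0.1, 0.2), function(eta) {
    pc <- power_curve("programmed", n_cysts = 15L, eta = eta,
                      replicates = reps, seed = 100 + round(100 * eta))
    cbind(truth = "programmed", eta = eta, pc)
  }),
  list(cbind(truth = "random", eta = NA,
             power_curve("random", n_cysts = 15L, replicates = reps,
                         seed = 999)))
))
print(rows, row.names = FALSE)
write_cystkit_csv(rows, "results/power_study.csv",
                  meta = list(replicates = reps, n_cysts = 15))
cat("written: results/power_study.csv\n")
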