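#!/usr/bin/env Rscript

# Stage 6: validation studies against the generator's ground truth.
#   (a) end-to-end recovery: how often the cluster nearest the occipital
#       plant is flagged significant for (valence, high) with a negative
#       theta coefficient, over independently simulated cohorts;
#   (b) familywise error on null cohorts (no planted effects);
#   (c) ICA separation quality across a sensor-noise ladder.
# scripts/acceptance.R runs (a) at 50 seeds and (b) at 200 replicates;
# here the defaults are lighter so the stage finishes in a few minutes.

library(icaffect)

n_seeds <- as.integer(Sys.getenv("N_SEEDS", "10"))
n_null <- as.integer(Sys.getenv("N_NULL", "100"))
dir.create("results", showWarnings = FALSE)

cat(sprintf("recovery study over %d cohorts...\n", n_seeds))
rec <- recovery_validation(n_seeds = n_seeds, seed = 20240915L)
write.csv(rec, "results/06_recovery.csv", row.names = FALSE)
cat(sprintf("  significant: %d/%d; theta sign correct: %d/%d; median centroid error %.1f mm\n",
            sum(rec$significant), n_seeds, sum(rec$sign_correct, na.rm = TRUE),
            n_seeds, median(rec$centroid_dist_mm, na.rm = TRUE)))

cat(sprintf("null familywise error over %d cohorts...\n", n_null))
nf <- null_fwer_validation(n_cohorts = n_null, seed = 20240916L)
cat("  per-family rates: ",
    paste(sprintf("%s=%.3f", names(nf$rates), nf$rates), collapse = ", "),
    sprintf(" (nominal alpha = 0.025)\n"))

cat("ICA separation across SNR ladder...\n")
am <- amari_snr_validation(n_seeds = 10, seed = 20240917L)
print(am)
write.csv(am, "results/06_amari_ladder.csv", row.names = FALSE)
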