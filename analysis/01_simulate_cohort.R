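#!/usr/bin/env Rscript

# Stage 1: simulate the demonstration cohort.
#
# Six participants view the 160-stimulus affective picture design
# (40 per circumplex quadrant, 8 sessions x 20 trials); their 16-channel,
# 96-Hz epoched EEG is generated from four cortical dipoles plus an
# ocular artifact.  Two effects are planted: log theta power of the
# occipital source falls with valence in high-valence states, and log
# alpha power of the right-parietal source falls with arousal in
# high-arousal states (slope 0.5 on standardized ratings).

library(icaffect)

seed <- 20240915L
dir.create("results", showWarnings = FALSE)

cfg <- demo_pipeline_config(seed = seed)
cohort_cfg <- cfg$cohort
cohort_cfg$seed <- icaffect:::derive_seed(seed, 20L)
cohort <- simulate_cohort(cohort_cfg)
print(cohort)

write_ratings_csv(cohort$stimuli, "results/ratings.csv")
saveRDS(list(cohort = cohort, config = cfg), "results/01_cohort.rds")

amp <- sapply(cohort$participants, function(p) mean(apply(p$epochs, 2, sd)))
cat(sprintf("mean channel RMS per participant: %s uV\n",
            paste(round(amp, 1), collapse = ", ")))
cat("wrote results/ratings.csv, results/01_cohort.rds\n")
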