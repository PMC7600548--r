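#!/usr/bin/env Rscript

# Stage 4: per retained cluster, compute log band-power features (Welch
# PSDs averaged across a participant's member ICs before the log) and
# run the four emotional-state-specific leave-one-participant-out
# regressions of the normative ratings.

library(icaffect)

state <- readRDS("results/01_cohort.rds")
cl <- readRDS("results/03_clusters.rds")
cfg <- state$config
stimuli <- state$cohort$stimuli

retained <- cl$clusters$summary$cluster[cl$clusters$summary$retained]
outcomes <- list()
for (c_ in retained) {
  mem <- cl$clusters$membership
  mem <- mem[!is.na(mem$cluster) & mem$cluster == c_, , drop = FALSE]
  cef <- aggregate_cluster_features(mem, cl$brain$activations,
                                    cl$brain$epoch_stimulus,
                                    cl$brain$sampling_rate)
  subsets <- split_by_state(cef, stimuli)
  for (nm in names(subsets)) {
    std <- standardize_per_participant(subsets[[nm]])
    outcomes[[nm]][[as.character(c_)]] <-
      lopo_regress(std, min_epochs = cfg$min_epochs)
  }
}

folds <- do.call(rbind, lapply(names(outcomes), function(nm) {
  do.call(rbind, lapply(names(outcomes[[nm]]), function(c_) {
    cbind(family = nm, cluster = c_, outcomes[[nm]][[c_]])
  }))
}))
write.csv(folds, "results/04_fold_metrics.csv", row.names = FALSE)
saveRDS(outcomes, "results/04_outcomes.rds")
cat(sprintf("regressed %d retained clusters x 4 families; fold table in results/04_fold_metrics.csv\n",
            length(retained)))
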