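#!/usr/bin/env Rscript

# Stage 3: cluster the cohort's brain components across participants by
# k-means in the 18-dimensional space (3 dipole coordinates, 10
# topography PCs, 5 ERP PCs), prune 3-SD outliers, and retain clusters
# present in a strict majority of participants.

library(icaffect)

state <- readRDS("results/01_cohort.rds")
results <- readRDS("results/02_decompositions.rds")
cfg <- state$config

brain <- collect_brain_ics(results)
feats <- build_features(brain, erp_window = cfg$erp_window,
                        n_topo_pcs = cfg$n_topo_pcs,
                        n_erp_pcs = cfg$n_erp_pcs, erp_len = cfg$erp_len)
cat(sprintf("topography PCs capture %.1f%% of variance; ERP PCs %.1f%%\n",
            100 * feats$topo_var_captured, 100 * feats$erp_var_captured))

clusters <- cluster_ics(feats, k = cfg$k,
                        n_participants = length(state$cohort$participants),
                        outlier_sd = cfg$outlier_sd,
                        seed = icaffect:::derive_seed(cfg$seed, 40L),
                        n_restarts = cfg$n_restarts)
print(clusters)

write.csv(clusters$summary, "results/03_clusters.csv", row.names = FALSE)
write.csv(clusters$membership, "results/03_membership.csv", row.names = FALSE)
saveRDS(list(brain = brain, features = feats, clusters = clusters),
        "results/03_clusters.rds")
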