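#!/usr/bin/env Rscript

# Stage 5: group-level inference.  Fold correlations are Fisher-z
# transformed, each cluster is tested with a one-tailed one-sample
# t-test, and p-values are Holm-corrected across clusters within each
# (axis, state) family at alpha = 0.025 (0.05 halved over the two states
# per axis).  Band coefficients are summarized in theta/alpha/beta/gamma
# order.

library(icaffect)

state <- readRDS("results/01_cohort.rds")
outcomes <- readRDS("results/04_outcomes.rds")
cfg <- state$config

rows <- list()
for (nm in names(outcomes)) {
  gs <- group_significance(outcomes[[nm]], alpha = cfg$alpha)
  parts <- strsplit(nm, "_")[[1]]
  gs$axis <- parts[1]; gs$state <- parts[2]
  for (c_ in gs$cluster) {
    cs <- coefficient_summary(outcomes[[nm]][[c_]])
    row <- gs[gs$cluster == c_, , drop = FALSE]
    for (b in seq_len(nrow(cs))) {
      row[[paste0("coef_", cs$band[b])]] <- cs$mean[b]
      row[[paste0("coef_sd_", cs$band[b])]] <- cs$sd[b]
    }
    rows[[length(rows) + 1L]] <- row
  }
}
final <- do.call(rbind, rows)
rownames(final) <- NULL
write.csv(final, "results/05_group_results.csv", row.names = FALSE)

cat("group-level results (one row per cluster x axis x state):\n")
print(format(final[, c("cluster", "axis", "state", "n_folds", "mean_r",
                       "mean_mse", "p_raw", "p_holm", "significant")],
             digits = 3), row.names = FALSE)
sig <- final[final$significant, ]
if (nrow(sig)) {
  cat("\nsignificant cluster-state pairs:\n")
  for (i in seq_len(nrow(sig))) {
    cat(sprintf(
      "  cluster %s, %s (%s state): mean r = %.3f, MSE = %.3f, Holm p = %.4f; coefficients (theta, alpha, beta, gamma) = %.2f, %.2f, %.2f, %.2f\n",
      sig$cluster[i], sig$axis[i], sig$state[i], sig$mean_r[i],
      sig$mean_mse[i], sig$p_holm[i], sig$coef_theta[i], sig$coef_alpha[i],
      sig$coef_beta[i], sig$coef_gamma[i]))
  }
}
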