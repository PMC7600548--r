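#!/usr/bin/env Rscript

# Stage 2: clean each participant's epochs, decompose into independent
# components, fit an equivalent dipole to every component topography and
# keep the brain components (residual variance <= 15%, inside the brain,
# no muscle-like spectrum or ocular topography).

library(icaffect)

state <- readRDS("results/01_cohort.rds")
cohort <- state$cohort
cfg <- state$config

grid <- make_dipole_grid(cohort$head_model, cfg$grid_step_mm)
results <- list()
for (rec in cohort$participants) {
  rec <- clean_epochs(rec, cfg$channel_z_thresh, cfg$epoch_ptp_thresh,
                      cfg$epoch_z_thresh)
  rep <- rec$cleaning_report
  dec <- suppressWarnings(run_ica(
    prepare_for_ica(rec), algorithm = cfg$algorithm,
    seed = icaffect:::derive_seed(cfg$seed, 30L + rec$participant_id),
    max_iter = cfg$ica_max_iter, max_samples = cfg$ica_max_samples))
  fits <- lapply(seq_len(dec$rank), function(j) {
    fit_dipole(dec$mixing[, j], cohort$head_model, grid = grid)
  })
  sel <- select_brain_ics(dec, fits, cohort$head_model)
  cat(sprintf(
    "participant %d: %d channels interpolated, %.1f%% epochs removed, %d/%d brain ICs\n",
    rec$participant_id, rep$n_channels_interpolated,
    100 * rep$fraction_epochs_removed, sum(sel$kept), dec$rank))
  results[[rec$participant_id]] <- list(
    participant_id = rec$participant_id, decomposition = dec,
    fits = fits, selection = sel, cleaning = rep)
}

sel_all <- do.call(rbind, lapply(results, function(r) {
  cbind(participant = r$participant_id, r$selection)
}))
write.csv(sel_all, "results/02_ic_selection.csv", row.names = FALSE)
saveRDS(results, "results/02_decompositions.rds")
cat(sprintf("cohort total: %d brain ICs (selection table in results/02_ic_selection.csv)\n",
            sum(sel_all$kept)))
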