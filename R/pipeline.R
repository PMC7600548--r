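#' Assemble a full pipeline configuration
#'
#' One serializable list drives every stage; all randomness flows from
#' `seed` via fixed per-stage offsets, so a run is reproducible from its
#' archived config alone.  `demo_pipeline_config()` is the scaled
#' configuration used by the worked examples and validation runs
#' (6 participants, 16 channels, 96 Hz, 4 planted cortical sources,
#' k = 4).
#'
#' @param cohort a `cohort_config` (used when `simulate = TRUE`).
#' @param simulate generate the cohort (`TRUE`) or read it from
#'   `input_dir`.
#' @param input_dir cohort container directory (see [write_cohort()]).
#' @param seed global seed; stage seeds are derived from it.
#' @param channel_z_thresh,epoch_ptp_thresh,epoch_z_thresh cleaning
#'   thresholds (see [clean_epochs()]).
#' @param algorithm,ica_max_iter,ica_tol,ica_max_samples ICA options
#'   (see [run_ica()]).
#' @param grid_step_mm,refine_tol dipole search options.
#' @param rv_max,brain_margin,psd_slope_band,frontal_frac_max brain-IC
#'   selection thresholds.
#' @param k,outlier_sd,n_restarts clustering options.
#' @param n_topo_pcs,n_erp_pcs,erp_len,erp_window feature options.
#' @param min_epochs minimum epochs per participant per state subset.
#' @param alpha familywise significance level (default 0.025).
#' @param out_dir optional output directory for tables and reports.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), simulate = TRUE,
                            input_dir = NULL, seed = 1L,
                            channel_z_thresh = 5, epoch_ptp_thresh = 200,
                            epoch_z_thresh = 4,
                            algorithm = "extended-infomax",
                            ica_max_iter = 200L, ica_tol = 1e-6,
                            ica_max_samples = 50000L,
                            grid_step_mm = 10, refine_tol = 0.5,
                            rv_max = 0.15, brain_margin = 0.9,
                            psd_slope_band = c(20, 45),
                            frontal_frac_max = 0.6,
                            k = 7L, outlier_sd = 3, n_restarts = 20L,
                            n_topo_pcs = 10L, n_erp_pcs = 5L,
                            erp_len = 128L, erp_window = c(0, 0.5),
                            min_epochs = 8L, alpha = 0.025,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param ... overrides passed to [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L,
                                 cohort = demo_cohort_config(
                                   seed = derive_seed(seed, 20L)), ...) {
  pipeline_config(cohort = cohort,
                  k = 4L, algorithm = "fixed-point-negentropy",
                  ica_max_iter = 30L, ica_max_samples = 30000L,
                  seed = seed, ...)
}

validate_pipeline_config <- function(cfg) {
  if (!isTRUE(cfg$simulate) && is.null(cfg$input_dir)) {
    stop_invalid("config error: simulate = FALSE requires `input_dir`")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_invalid("`alpha` must be in (0, 1)")
  invisible(cfg)
}

#' Run the full source-space emotion-regression pipeline
#'
#' Executes simulate (or load) -> clean -> average-reference/rank-reduce
#' -> ICA -> dipole fit and brain-IC selection -> cross-participant
#' clustering -> band-power features -> state-specific
#' leave-one-participant-out regression -> Fisher-z group statistics with
#' Holm-Bonferroni correction, and assembles one results row per
#' (retained cluster, axis, state).  Exit reflects completion, not
#' significance; any stage failure propagates with the stage name.
#'
#' @param config a `pipeline_config`.
#' @return list of class `pipeline_run`: `results` (the final table),
#'   `group_stats` (per-family tables), `clusters`, `selection`,
#'   `cleaning`, `stimuli`, `config`, plus per-stage bookkeeping counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    if (isTRUE(config$simulate)) {
      cc <- config$cohort
      cc$seed <- derive_seed(config$seed, 20L)
      simulate_cohort(cc)
    } else {
      read_cohort(config$input_dir)
    }
  })
  model <- cohort$head_model
  stimuli <- cohort$stimuli

  participant_results <- vector("list", length(cohort$participants))
  cleaning <- list()
  grid <- stage("localize", make_dipole_grid(model, config$grid_step_mm))
  for (i in seq_along(cohort$participants)) {
    rec <- cohort$participants[[i]]
    rec <- stage("preprocess", clean_epochs(
      rec, channel_z_thresh = config$channel_z_thresh,
      epoch_ptp_thresh = config$epoch_ptp_thresh,
      epoch_z_thresh = config$epoch_z_thresh))
    cleaning[[as.character(rec$participant_id)]] <- rec$cleaning_report
    prep <- stage("preprocess", prepare_for_ica(rec))
    dec <- stage("decompose", run_ica(
      prep, algorithm = config$algorithm,
      seed = derive_seed(config$seed, 30L + i),
      max_iter = config$ica_max_iter, tol = config$ica_tol,
      max_samples = config$ica_max_samples))
    fits <- stage("localize", lapply(seq_len(dec$rank), function(j) {
      fit_dipole(dec$mixing[, j], model, grid_step_mm = config$grid_step_mm,
                 refine_tol = config$refine_tol, grid = grid)
    }))
    sel <- stage("localize", select_brain_ics(
      dec, fits, model, rv_max = config$rv_max,
      brain_margin = config$brain_margin,
      psd_slope_band = config$psd_slope_band,
      frontal_frac_max = config$frontal_frac_max))
    participant_results[[i]] <- list(participant_id = rec$participant_id,
                                     decomposition = dec, fits = fits,
                                     selection = sel)
  }

  brain <- stage("cluster", collect_brain_ics(participant_results))
  feats <- stage("cluster", build_features(
    brain, erp_window = config$erp_window, n_topo_pcs = config$n_topo_pcs,
    n_erp_pcs = config$n_erp_pcs, erp_len = config$erp_len))
  clusters <- stage("cluster", cluster_ics(
    feats, k = config$k, n_participants = length(cohort$participants),
    outlier_sd = config$outlier_sd, seed = derive_seed(config$seed, 40L),
    n_restarts = config$n_restarts))

  retained <- clusters$summary$cluster[clusters$summary$retained]
  families <- expand.grid(axis = c("valence", "arousal"),
                          state = c("high", "low"),
                          stringsAsFactors = FALSE)
  outcomes <- list(); group <- list(); results <- list()
  for (cl in retained) {
    mem <- clusters$membership
    mem <- mem[!is.na(mem$cluster) & mem$cluster == cl, , drop = FALSE]
    cef <- stage("features", aggregate_cluster_features(
      mem, brain$activations, brain$epoch_stimulus, brain$sampling_rate))
    subsets <- stage("regress", split_by_state(cef, stimuli))
    for (nm in names(subsets)) {
      std <- stage("regress", standardize_per_participant(subsets[[nm]]))
      outcomes[[nm]][[as.character(cl)]] <-
        stage("regress", lopo_regress(std, min_epochs = config$min_epochs))
    }
  }
  for (f in seq_len(nrow(families))) {
    nm <- paste(families$axis[f], families$state[f], sep = "_")
    if (is.null(outcomes[[nm]])) next
    gs <- stage("stats", group_significance(outcomes[[nm]], alpha = config$alpha))
    gs$axis <- families$axis[f]
    gs$state <- families$state[f]
    group[[nm]] <- gs
    for (cl in gs$cluster) {
      cs <- coefficient_summary(outcomes[[nm]][[cl]])
      row <- gs[gs$cluster == cl, , drop = FALSE]
      for (b in seq_len(nrow(cs))) {
        row[[paste0("coef_", cs$band[b])]] <- cs$mean[b]
        row[[paste0("coef_sd_", cs$band[b])]] <- cs$sd[b]
      }
      results[[length(results) + 1L]] <- row
    }
  }
  results <- if (length(results)) do.call(rbind, results) else NULL
  if (!is.null(results)) {
    results <- results[, c("cluster", "axis", "state",
                           setdiff(names(results), c("cluster", "axis", "state")))]
    rownames(results) <- NULL
  }

  run <- structure(list(
    results = results, group_stats = group, outcomes = outcomes,
    clusters = clusters, features = feats,
    selection = lapply(participant_results, `[[`, "selection"),
    cleaning = cleaning, stimuli = stimuli, config = config,
    n_brain_ics = nrow(brain$provenance),
    brain_ics = brain),
    class = "pipeline_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d brain ICs, %d/%d clusters retained\n",
              x$n_brain_ics, sum(x$clusters$summary$retained),
              x$clusters$k))
  if (!is.null(x$results)) {
    cols <- c("cluster", "axis", "state", "n_folds", "mean_r", "mean_mse",
              "p_holm", "significant")
    print(format(x$results[, cols], digits = 3), row.names = FALSE)
  }
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$results)) {
    utils::write.csv(run$results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(run$results, file.path(out_dir, "results.json"),
                         dataframe = "rows", digits = NA)
  }
  jsonlite::write_json(run$clusters$summary,
                       file.path(out_dir, "clusters.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(run$cleaning, file.path(out_dir, "cleaning.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- run$config
  cfg$cohort$sources <- lapply(cfg$cohort$sources, unclass)
  yaml::write_yaml(lapply(unclass(cfg), function(v) {
    if (inherits(v, "cohort_config")) unclass(v) else v
  }), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
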