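#' End-to-end planted-effect recovery study
#'
#' Runs the full pipeline on independently simulated scaled cohorts
#' (the `demo_pipeline_config()` conditions: 6 participants, 160 epochs,
#' 16 channels, 4 planted cortical sources plus an ocular artifact) and,
#' for each seed, asks whether the cluster nearest the occipital source
#' that carries the planted (valence, high-state) theta slope is flagged
#' significant for that family, and whether its mean fitted theta
#' coefficient has the planted (negative) sign.
#'
#' @param n_seeds number of independent cohorts.
#' @param seed base seed.
#' @param quiet suppress per-seed progress.
#' @return data.frame with one row per seed: `seed`, `retained`,
#'   `n_folds`, `centroid_dist_mm`, `mean_r`, `theta_coef`,
#'   `significant`, `sign_correct`.
#' @export
recovery_validation <- function(n_seeds = 50L, seed = 1L, quiet = TRUE) {
  target <- default_sources()[[1L]]$location  # occipital, theta plant
  rows <- lapply(seq_len(n_seeds), function(i) {
    s <- derive_seed(seed, 500L + i)
    run <- suppressWarnings(run_pipeline(demo_pipeline_config(seed = s)))
    st <- run$clusters$summary
    st <- st[st$retained, , drop = FALSE]
    out <- data.frame(seed = s, retained = nrow(st) > 0, n_folds = NA_integer_,
                      centroid_dist_mm = NA_real_, mean_r = NA_real_,
                      theta_coef = NA_real_, significant = FALSE,
                      sign_correct = NA)
    if (nrow(st) > 0) {
      d <- sqrt((st$centroid_x - target[1])^2 + (st$centroid_y - target[2])^2 +
                  (st$centroid_z - target[3])^2)
      cl <- as.character(st$cluster[which.min(d)])
      gs <- run$group_stats$valence_high
      row <- gs[gs$cluster == cl, , drop = FALSE]
      cs <- coefficient_summary(run$outcomes$valence_high[[cl]])
      out$centroid_dist_mm <- min(d)
      out$n_folds <- row$n_folds
      out$mean_r <- row$mean_r
      out$theta_coef <- cs$mean[cs$band == "theta"]
      out$significant <- isTRUE(row$significant)
      out$sign_correct <- out$theta_coef < 0
    }
    if (!quiet) {
      message(sprintf("seed %d: significant=%s theta=%.3f", i,
                      out$significant, out$theta_coef))
    }
    out
  })
  do.call(rbind, rows)
}

#' Familywise type-I error on null cohorts
#'
#' Simulates cohorts at the regression-input level whose band-power
#' features are independent of the ratings (the generator's all-zero
#' slope case collapsed to the feature table it induces), runs the
#' state-specific leave-one-participant-out regressions for `n_clusters`
#' clusters and the Fisher-z/Holm group test per (axis, state) family,
#' and records whether any cluster in the family is rejected.
#'
#' @param n_cohorts number of null replicates (default 200).
#' @param seed base seed.
#' @param n_participants cohort size (default 6).
#' @param n_per_quadrant stimuli per quadrant (default 20: 40 epochs per
#'   state subset).
#' @param n_clusters clusters per family (default 3).
#' @param alpha familywise level (default 0.025).
#' @return list with `rates` (named per-family familywise rejection
#'   rate), `pooled` (mean over families), and `n_cohorts`.
#' @export
null_fwer_validation <- function(n_cohorts = 200L, seed = 1L,
                                 n_participants = 6L, n_per_quadrant = 20L,
                                 n_clusters = 3L, alpha = 0.025) {
  fam <- c("valence_high", "valence_low", "arousal_high", "arousal_low")
  rej <- matrix(FALSE, n_cohorts, length(fam), dimnames = list(NULL, fam))
  bands <- band_definitions()$name
  for (i in seq_len(n_cohorts)) {
    rng <- local_rng(derive_seed(seed, 2000L + i))
    stim <- generate_stimulus_set(n_per_quadrant,
                                  seed = derive_seed(seed, 4000L + i))
    n_ep <- nrow(stim)
    for (f in fam) {
      outcomes <- list()
      for (cl in seq_len(n_clusters)) {
        feats <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
          df <- data.frame(participant = p, epoch = seq_len(n_ep),
                           stimulus_id = stim$stimulus_id)
          df[bands] <- matrix(stats::rnorm(n_ep * 4L), n_ep)
          df
        }))
        subs <- split_by_state(feats, stim)
        tab <- standardize_per_participant(subs[[f]])
        outcomes[[as.character(cl)]] <- lopo_regress(tab, min_epochs = 8L)
      }
      gs <- group_significance(outcomes, alpha = alpha)
      rej[i, f] <- any(gs$significant)
    }
    rng$restore()
  }
  rates <- colMeans(rej)
  list(rates = rates, pooled = mean(rates), n_cohorts = n_cohorts)
}

#' Separation quality across a sensor-noise ladder
#'
#' Mixes super-Gaussian sources, adds white sensor noise at each SNR of
#' the ladder, and reports the mean Amari index between the estimated
#' unmixing and the true mixing over independent seeds.  Separation
#' quality should improve (index decrease) monotonically with SNR.
#'
#' @param snrs SNR ladder (variance ratio).
#' @param n_seeds seeds per rung (default 10).
#' @param n_sources,n_samples mixture size.
#' @param seed base seed.
#' @param algorithm ICA algorithm.
#' @return data.frame with `snr` and `mean_amari`.
#' @export
amari_snr_validation <- function(snrs = c(2, 10, 50), n_seeds = 10L,
                                 n_sources = 6L, n_samples = 10000L,
                                 seed = 1L,
                                 algorithm = "extended-infomax") {
  res <- vapply(snrs, function(snr) {
    mean(vapply(seq_len(n_seeds), function(i) {
      rng <- local_rng(derive_seed(seed, 3000L + i))
      S <- matrix(stats::rexp(n_sources * n_samples) *
                    sample(c(-1, 1), n_sources * n_samples, replace = TRUE),
                  n_sources)
      A <- matrix(stats::rnorm(n_sources^2), n_sources)
      X <- A %*% S
      X <- X + sqrt(mean(X^2) / snr) * matrix(stats::rnorm(length(X)),
                                              n_sources)
      rng$restore()
      dec <- suppressWarnings(run_ica(X, algorithm = algorithm,
                                      seed = derive_seed(seed, 100L + i),
                                      max_iter = 150L))
      amari_index(dec$unmixing, A)
    }, numeric(1)))
  }, numeric(1))
  data.frame(snr = snrs, mean_amari = res)
}
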