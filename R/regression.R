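#' Split cluster epoch features by emotional state
#'
#' Builds the four regression tables: valence in the high-valence state
#' (ratings > 5), valence low (< 5), arousal high, arousal low.  High and
#' low partition each axis; a rating exactly at the neutral value 5 is
#' excluded with a warning (the generator never produces one).  Each
#' table carries the axis rating as the `rating` column.
#'
#' @param features a ClusterEpochFeatures table from
#'   [aggregate_cluster_features()].
#' @param stimuli the stimulus ratings table.
#' @return named list of four data.frames
#'   (`valence_high`, `valence_low`, `arousal_high`, `arousal_low`),
#'   each with attribute `axis` and `state`.
#' @export
split_by_state <- function(features, stimuli) {
  m <- match(features$stimulus_id, stimuli$stimulus_id)
  if (any(is.na(m))) stop_invalid("epochs with unknown stimulus_id")
  out <- list()
  for (axis in c("valence", "arousal")) {
    r <- stimuli[[axis]][m]
    if (any(r == 5)) {
      warning(sprintf("%d epochs with neutral %s rating (= 5) excluded",
                      sum(r == 5), axis))
    }
    for (state in c("high", "low")) {
      keep <- if (state == "high") r > 5 else r < 5
      df <- features[keep, , drop = FALSE]
      df$rating <- r[keep]
      attr(df, "axis") <- axis
      attr(df, "state") <- state
      out[[paste(axis, state, sep = "_")]] <- df
    }
  }
  out
}

#' Standardize features and rating within each participant
#'
#' Within each participant's rows, each band feature and the rating are
#' centred to mean 0 and scaled to variance 1, with the population
#' (1/n) variance convention so that "variance 1" holds exactly.
#' Idempotent, and invariant to affine rescaling of any input column.
#'
#' @param table a state-subset table with columns `participant`,
#'   the four band features, and `rating`.
#' @param columns columns to standardize.
#' @return the table with standardized columns.
#' @export
standardize_per_participant <- function(table,
                                        columns = c(band_definitions()$name,
                                                    "rating")) {
  for (p in unique(table$participant)) {
    ix <- which(table$participant == p)
    if (length(ix) < 2L) {
      stop_invalid("participant %s has fewer than 2 epochs", p)
    }
    table[ix, columns] <- scale_pop(as.matrix(table[ix, columns]))
  }
  table
}

#' Leave-one-participant-out regression of emotional ratings
#'
#' For every participant p in the table, fits one ordinary-least-squares
#' model (four band predictors plus intercept) on the pooled standardized
#' epochs of all *other* participants, predicts p's epochs, and records
#' the Pearson correlation between predictions and p's standardized
#' ratings, the mean squared error, and the fitted coefficients.  The
#' held-out participant's data is never seen at fit time.  Folds whose
#' predictions or targets are constant (undefined correlation) are
#' flagged and excluded from summaries, with a warning.
#'
#' @param table standardized state-subset table (from
#'   [standardize_per_participant()]).
#' @param min_epochs minimum epochs per participant (default 8).
#' @return data.frame of class `regression_outcome`, one row per fold:
#'   `participant`, `r`, `mse`, `intercept`, `theta`, `alpha`, `beta`,
#'   `gamma`, `defined`; attributes `axis`/`state` are carried through.
#' @export
lopo_regress <- function(table, min_epochs = 8L) {
  bands <- band_definitions()$name
  participants <- sort(unique(table$participant))
  if (length(participants) < 3L) {
    stop_invalid("need at least 3 participants, got %d", length(participants))
  }
  counts <- table(table$participant)
  if (any(counts < min_epochs)) {
    stop_invalid("every participant needs at least %d epochs per subset",
                 min_epochs)
  }
  rows <- lapply(participants, function(p) {
    train <- table[table$participant != p, , drop = FALSE]
    test <- table[table$participant == p, , drop = FALSE]
    Xtr <- cbind(1, as.matrix(train[, bands]))
    fit <- stats::lm.fit(Xtr, train$rating)
    beta <- fit$coefficients
    pred <- as.numeric(cbind(1, as.matrix(test[, bands])) %*% beta)
    defined <- stats::sd(pred) > 0 && stats::sd(test$rating) > 0
    data.frame(participant = p,
               r = if (defined) stats::cor(pred, test$rating) else NA_real_,
               mse = mean((pred - test$rating)^2),
               intercept = beta[1L],
               theta = beta[2L], alpha = beta[3L],
               beta = beta[4L], gamma = beta[5L],
               defined = defined)
  })
  out <- do.call(rbind, rows)
  if (any(!out$defined)) {
    warning(sprintf("%d fold(s) with undefined correlation excluded from summaries",
                    sum(!out$defined)))
  }
  attr(out, "axis") <- attr(table, "axis")
  attr(out, "state") <- attr(table, "state")
  class(out) <- c("regression_outcome", "data.frame")
  out
}
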