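bands <- c("theta", "alpha", "beta", "gamma")

fake_cluster_features <- function(stimuli, n_participants = 4,
                                  effect = NULL, noise = 1, seed = 1) {
  set.seed(seed)
  out <- list()
  for (p in seq_len(n_participants)) {
    df <- data.frame(participant = p, epoch = seq_len(nrow(stimuli)),
                     stimulus_id = stimuli$stimulus_id)
    X <- matrix(rnorm(nrow(stimuli) * 4, sd = noise), ncol = 4)
    if (!is.null(effect)) X <- X + effect(stimuli)
    df[bands] <- X
    out[[p]] <- df
  }
  do.call(rbind, out)
}

test_that("state splitting partitions each axis at the neutral point", {
  stim <- generate_stimulus_set(40, seed = 1)
  feats <- fake_cluster_features(stim, n_participants = 2)
  subs <- split_by_state(feats, stim)
  expect_named(subs, c("valence_high", "valence_low",
                       "arousal_high", "arousal_low"))
  for (nm in names(subs)) {
    expect_equal(nrow(subs[[nm]]), 2 * 80L)  # 2 quadrants x 40, per participant
  }
  # high/low partition per axis
  expect_equal(sort(c(subs$valence_high$epoch[subs$valence_high$participant == 1],
                      subs$valence_low$epoch[subs$valence_low$participant == 1])),
               seq_len(160))
  # HVHA epochs appear in exactly the two high subsets
  hvha <- stim$stimulus_id[stim$quadrant == "HVHA"]
  expect_true(all(hvha %in% subs$valence_high$stimulus_id))
  expect_true(all(hvha %in% subs$arousal_high$stimulus_id))
  expect_false(any(hvha %in% subs$valence_low$stimulus_id))
  expect_false(any(hvha %in% subs$arousal_low$stimulus_id))
  expect_equal(attr(subs$arousal_low, "axis"), "arousal")
  expect_equal(attr(subs$arousal_low, "state"), "low")
})

test_that("neutral ratings are excluded with a warning, empty subsets flagged", {
  stim <- data.frame(stimulus_id = 1:4, valence = c(6, 7, 5, 8),
                     arousal = c(6, 7, 6.5, 8))
  feats <- data.frame(participant = 1, epoch = 1:4, stimulus_id = 1:4)
  feats[bands] <- matrix(rnorm(16), 4)
  expect_warning(subs <- split_by_state(feats, stim), "neutral")
  expect_equal(nrow(subs$valence_high), 3L)
  expect_equal(nrow(subs$valence_low), 0L)  # all-high toy set
})

test_that("per-participant standardization is exact, idempotent, affine-invariant", {
  stim <- generate_stimulus_set(10, seed = 2)
  feats <- fake_cluster_features(stim, n_participants = 3, seed = 3)
  subs <- split_by_state(feats, stim)
  std <- standardize_per_participant(subs$valence_high)
  for (p in 1:3) {
    M <- as.matrix(std[std$participant == p, c(bands, "rating")])
    expect_lt(max(abs(colMeans(M))), 1e-12)
    expect_equal(unname(colMeans(M^2)), rep(1, 5), tolerance = 1e-12)
  }
  expect_equal(standardize_per_participant(std), std, tolerance = 1e-12)
  shifted <- subs$valence_high
  shifted$theta <- 10 * shifted$theta + 3
  expect_equal(standardize_per_participant(shifted), std,
               tolerance = 1e-12)
})

test_that("zero-variance columns abort with the column named", {
  df <- data.frame(participant = rep(1, 10), epoch = 1:10,
                   stimulus_id = 1:10, theta = rnorm(10), alpha = rnorm(10),
                   beta = 1, gamma = rnorm(10), rating = rnorm(10))
  expect_error(standardize_per_participant(df), "beta")
})

test_that("a noiseless linear target gives perfect folds", {
  stim <- generate_stimulus_set(10, seed = 4)
  feats <- fake_cluster_features(stim, n_participants = 4, seed = 5)
  subs <- split_by_state(feats, stim)
  tab <- standardize_per_participant(subs$valence_high)
  # target exactly linear in the standardized features, same everywhere
  tab$rating <- with(tab, 0.5 * theta - 0.3 * alpha + 0.2 * beta - gamma)
  out <- lopo_regress(tab)
  expect_equal(nrow(out), 4L)
  expect_equal(out$r, rep(1, 4), tolerance = 1e-8)
  expect_lt(max(out$mse), 1e-10)
  expect_true(all(out$defined))
})

test_that("OLS folds match the normal equations and have no intercept", {
  stim <- generate_stimulus_set(10, seed = 6)
  feats <- fake_cluster_features(
    stim, n_participants = 3,
    effect = function(s) cbind(-0.4 * scale(s$valence)[, 1], 0, 0, 0),
    seed = 7)
  subs <- split_by_state(feats, stim)
  tab <- standardize_per_participant(subs$valence_high)
  out <- lopo_regress(tab)
  for (i in seq_len(nrow(out))) {
    p <- out$participant[i]
    train <- tab[tab$participant != p, ]
    X <- cbind(1, as.matrix(train[bands]))
    beta_hat <- solve(crossprod(X), crossprod(X, train$rating))
    expect_equal(as.numeric(out[i, c("intercept", bands)]),
                 as.numeric(beta_hat), tolerance = 1e-8)
    # balanced standardized training folds: intercept vanishes
    expect_lt(abs(out$intercept[i]), 1e-10)
  }
})

test_that("the held-out participant's data never enters the fit", {
  stim <- generate_stimulus_set(10, seed = 8)
  feats <- fake_cluster_features(stim, n_participants = 4, seed = 9)
  subs <- split_by_state(feats, stim)
  tab <- standardize_per_participant(subs$arousal_high)
  out <- lopo_regress(tab)
  # corrupt participant 2's feature rows (keeping them standardized)
  set.seed(13)
  tab2 <- tab
  ix <- tab2$participant == 2
  tab2[ix, bands] <- tab2[sample(which(ix)), bands]
  out2 <- lopo_regress(tab2)
  # fold 2's coefficients are fit on participants 1, 3, 4 only: unchanged
  expect_equal(as.numeric(out2[out2$participant == 2, c("intercept", bands)]),
               as.numeric(out[out$participant == 2, c("intercept", bands)]),
               tolerance = 1e-12)
  # the other folds trained on participant 2 do change
  expect_false(isTRUE(all.equal(
    as.numeric(out2[out2$participant == 1, bands]),
    as.numeric(out[out$participant == 1, bands]), tolerance = 1e-12)))
})

test_that("null features give near-zero mean correlation across folds", {
  stim <- generate_stimulus_set(10, seed = 10)
  rs <- vapply(1:20, function(s) {
    feats <- fake_cluster_features(stim, n_participants = 4, seed = 100 + s)
    subs <- split_by_state(feats, stim)
    tab <- standardize_per_participant(subs$valence_high)
    mean(lopo_regress(tab)$r)
  }, numeric(1))
  n_folds <- 4; n_epochs <- 20
  expect_lt(abs(mean(rs)), 3 / sqrt(20 * n_folds * n_epochs))
})

test_that("degenerate fold inputs are flagged or rejected", {
  stim <- generate_stimulus_set(10, seed = 11)
  feats <- fake_cluster_features(stim, n_participants = 2, seed = 12)
  subs <- split_by_state(feats, stim)
  expect_error(lopo_regress(standardize_per_participant(subs$valence_high)),
               "3 participants")
})
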