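# Synthetic cohort of brain ICs with controllable topographies/ERPs.
fake_brain_ics <- function(n_ic = 20, n_ch = 16, n_ep = 6, n_samp = 96,
                           fs = 96, n_participants = 10, seed = 1) {
  set.seed(seed)
  prov <- data.frame(participant = rep(seq_len(n_participants),
                                       length.out = n_ic),
                     ic = 1L)
  prov$ic <- ave(prov$participant, prov$participant, FUN = seq_along)
  acts <- list()
  for (p in unique(prov$participant)) {
    k <- sum(prov$participant == p)
    acts[[as.character(p)]] <- array(rnorm(k * n_ep * n_samp),
                                     c(k, n_ep, n_samp))
  }
  structure(list(
    provenance = prov,
    topographies = matrix(rnorm(n_ic * n_ch), n_ic),
    locations = matrix(runif(n_ic * 3, -50, 50), n_ic),
    activations = acts,
    epoch_stimulus = setNames(rep(list(seq_len(n_ep)),
                                  length(unique(prov$participant))),
                              as.character(unique(prov$participant))),
    sampling_rate = fs), class = "brain_ics")
}

test_that("feature vectors have 18 dimensions with standardized blocks", {
  b <- fake_brain_ics()
  f <- build_features(b)
  expect_equal(dim(f$features), c(20L, 18L))
  expect_equal(unname(colMeans(f$features)), rep(0, 18), tolerance = 1e-10)
  expect_equal(unname(apply(f$features, 2, function(v) mean(v^2))),
               rep(1, 18), tolerance = 1e-10)
  expect_equal(colnames(f$features)[1:3], c("dip_x", "dip_y", "dip_z"))
})

test_that("identical ICs receive identical feature vectors", {
  b <- fake_brain_ics(n_ic = 14, n_participants = 7, seed = 2)
  # make ICs 3 and 10 exact clones (topography, location, activations)
  b$topographies[10, ] <- b$topographies[3, ]
  b$locations[10, ] <- b$locations[3, ]
  p3 <- as.character(b$provenance$participant[3])
  p10 <- as.character(b$provenance$participant[10])
  b$activations[[p10]][b$provenance$ic[10], , ] <-
    b$activations[[p3]][b$provenance$ic[3], , ]
  f <- build_features(b)
  expect_equal(f$features[10, ], f$features[3, ], tolerance = 1e-10)
})

test_that("retained topography PCs capture the eigenvalue share exactly", {
  b <- fake_brain_ics(n_ic = 30, n_ch = 24, n_participants = 10, seed = 3)
  f <- build_features(b)
  ev <- eigen(cov(b$topographies), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(f$topo_var_captured, sum(ev[1:10]) / sum(ev),
               tolerance = 1e-8)
})

test_that("too few cohort ICs for the retained PCs is an error", {
  b <- fake_brain_ics(n_ic = 9, n_participants = 9, seed = 4)
  expect_error(build_features(b), "at least")
})

fake_features <- function(X, participants, seed = 1) {
  n <- nrow(X)
  structure(list(features = X,
                 provenance = data.frame(participant = participants,
                                         ic = seq_len(n)),
                 locations = matrix(runif(n * 3, -40, 40), n)),
            class = "ic_features")
}

test_that("well-separated blobs are clustered exactly", {
  set.seed(5)
  centers <- matrix(rnorm(3 * 18, sd = 1), 3) * 10
  lab <- rep(1:3, each = 12)
  X <- centers[lab, ] + matrix(rnorm(36 * 18, sd = 0.3), 36)
  f <- fake_features(X, participants = rep(1:12, 3))
  cl <- cluster_ics(f, k = 3, n_participants = 12, seed = 2)
  # align by the globally unique ic index, then require a one-to-one
  # correspondence between true blob labels and cluster labels
  got <- cl$membership$cluster[match(seq_len(36), cl$membership$ic)]
  expect_equal(length(unique(paste(lab, got))), 3L)
  expect_true(all(cl$summary$retained))
})

test_that("an extreme member is pruned as an outlier", {
  set.seed(6)
  X <- matrix(rnorm(30 * 18, sd = 1), 30)
  X[1:15, 1] <- X[1:15, 1] + 15
  X[16:30, 1] <- X[16:30, 1] - 15
  base_d <- sqrt(18)  # typical member distance scale
  # displace one member of the second blob orthogonally to the blob axis,
  # 12 in-cluster SDs out: far enough to prune, near enough that k-means
  # still assigns it to its blob rather than isolating it
  X[30, ] <- colMeans(X[16:29, , drop = FALSE]) + c(0, 12 * base_d, rep(0, 16))
  f <- fake_features(X, participants = rep(1:15, 2))
  cl <- cluster_ics(f, k = 2, n_participants = 15, seed = 3)
  row30 <- match(30L, cl$membership$ic)
  expect_true(cl$membership$outlier[row30])
  expect_true(is.na(cl$membership$cluster[row30]))
  expect_equal(sum(cl$membership$outlier), 1L)
})

test_that("majority-participant retention uses a strict majority", {
  set.seed(7)
  # blob A: 13 distinct participants; blob B: 12 distinct participants
  XA <- matrix(rnorm(13 * 18, sd = 0.4), 13) + 8
  XB <- matrix(rnorm(12 * 18, sd = 0.4), 12) - 8
  f <- fake_features(rbind(XA, XB), participants = c(1:13, 1:12))
  cl <- cluster_ics(f, k = 2, n_participants = 25, seed = 4)
  s <- cl$summary[order(cl$summary$n_participants, decreasing = TRUE), ]
  expect_equal(s$n_participants, c(13L, 12L))
  expect_equal(s$retained, c(TRUE, FALSE))  # 13 > 12.5, 12 < 12.5
})

test_that("clustering is invariant to the order ICs are supplied", {
  set.seed(8)
  centers <- matrix(rnorm(2 * 18), 2) * 8
  lab <- rep(1:2, each = 10)
  X <- centers[lab, ] + matrix(rnorm(20 * 18, sd = 0.5), 20)
  f1 <- fake_features(X, participants = rep(1:10, 2))
  perm <- sample(20)
  f2 <- f1
  f2$features <- f1$features[perm, ]
  f2$provenance <- f1$provenance[perm, ]
  f2$locations <- f1$locations[perm, ]
  c1 <- cluster_ics(f1, k = 2, n_participants = 10, seed = 5)
  c2 <- cluster_ics(f2, k = 2, n_participants = 10, seed = 5)
  o1 <- order(c1$membership$participant, c1$membership$ic)
  o2 <- order(c2$membership$participant, c2$membership$ic)
  expect_equal(c1$membership$cluster[o1], c2$membership$cluster[o2])
  expect_equal(c1$summary$centroid_x, c2$summary$centroid_x,
               tolerance = 1e-10)
})

test_that("degenerate k values are rejected", {
  f <- fake_features(matrix(rnorm(10 * 18), 10), participants = 1:10)
  expect_error(cluster_ics(f, k = 1, n_participants = 10, seed = 1), "k")
  expect_error(cluster_ics(f, k = 10, n_participants = 10, seed = 1),
               "smaller")
})
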