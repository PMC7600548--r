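#' Collect kept brain ICs across a cohort
#'
#' Assembles the per-participant decompositions, dipole fits and
#' selections into one table of brain ICs with everything the clustering
#' and feature stages need.
#'
#' @param participant_results list; each element has `participant_id`,
#'   `decomposition`, `fits`, `selection`.
#' @return list of class `brain_ics`: `provenance` (data.frame
#'   participant, ic), `topographies` (ICs x channels), `locations`
#'   (ICs x 3), `activations` (named list of `ics x epochs x samples`
#'   arrays per participant), `epoch_stimulus` (named list),
#'   `sampling_rate`.
#' @export
collect_brain_ics <- function(participant_results) {
  prov <- list(); topo <- list(); loc <- list()
  acts <- list(); stim <- list()
  fs <- NULL
  for (res in participant_results) {
    dec <- res$decomposition
    kept <- res$selection$ic[res$selection$kept]
    fs <- fs %||% dec$sampling_rate
    p <- as.character(res$participant_id)
    a <- array(t(dec$activations),
               c(dec$samples_per_epoch, dec$n_epochs, dec$rank))
    acts[[p]] <- aperm(a, c(3L, 2L, 1L))  # ic x epoch x sample
    stim[[p]] <- dec$epoch_stimulus
    for (i in kept) {
      prov[[length(prov) + 1L]] <- data.frame(participant = res$participant_id,
                                              ic = i)
      topo[[length(topo) + 1L]] <- dec$mixing[, i]
      loc[[length(loc) + 1L]] <- res$fits[[i]]$location
    }
  }
  if (length(prov) == 0L) stop_invalid("no brain ICs were kept in this cohort")
  structure(list(provenance = do.call(rbind, prov),
                 topographies = do.call(rbind, topo),
                 locations = do.call(rbind, loc),
                 activations = acts, epoch_stimulus = stim,
                 sampling_rate = fs),
            class = "brain_ics")
}

#' Build the 18-dimensional clustering feature vectors
#'
#' Per brain IC: 3 dipole-location values, the scores of the topography
#' on the top `n_topo_pcs` principal components of all cohort
#' topographies, and the scores of the 0-500 ms ERP (across-epoch mean
#' activation, resampled to `erp_len` points) on the top `n_erp_pcs`
#' ERP principal components.  Each block is standardized across ICs
#' (per-dimension mean 0, variance 1) and the blocks are concatenated in
#' the order (dipole, topography, ERP), giving 18 dimensions at the
#' defaults.
#'
#' @param brain_ics a `brain_ics` collection.
#' @param erp_window ERP window in seconds (default `c(0, 0.5)`).
#' @param n_topo_pcs,n_erp_pcs retained principal components (10 and 5).
#' @param erp_len fixed ERP resampling length (default 128).
#' @return list of class `ic_features`: `features` (ICs x 18 matrix),
#'   `provenance`, `locations`, plus the fitted PCA rotations and the
#'   per-block captured variance fractions.
#' @export
build_features <- function(brain_ics, erp_window = c(0, 0.5),
                           n_topo_pcs = 10L, n_erp_pcs = 5L,
                           erp_len = 128L) {
  n_ic <- nrow(brain_ics$provenance)
  if (n_ic < max(n_topo_pcs, n_erp_pcs) + 1L) {
    stop_invalid("need at least %d cohort ICs for %d principal components, got %d",
                 max(n_topo_pcs, n_erp_pcs) + 1L, max(n_topo_pcs, n_erp_pcs),
                 n_ic)
  }
  fs <- brain_ics$sampling_rate
  w0 <- max(1L, 1L + round(erp_window[1L] * fs))
  w1 <- round(erp_window[2L] * fs)

  erps <- t(vapply(seq_len(n_ic), function(i) {
    p <- as.character(brain_ics$provenance$participant[i])
    ic <- brain_ics$provenance$ic[i]
    a <- brain_ics$activations[[p]][ic, , w0:w1, drop = FALSE]
    erp <- colMeans(a[1L, , ])
    stats::approx(seq_along(erp), erp, n = erp_len)$y
  }, numeric(erp_len)))

  topo_pca <- stats::prcomp(brain_ics$topographies, center = TRUE,
                            scale. = FALSE)
  erp_pca <- stats::prcomp(erps, center = TRUE, scale. = FALSE)
  topo_scores <- topo_pca$x[, seq_len(n_topo_pcs), drop = FALSE]
  erp_scores <- erp_pca$x[, seq_len(n_erp_pcs), drop = FALSE]

  blocks <- cbind(scale_pop(brain_ics$locations),
                  scale_pop(topo_scores),
                  scale_pop(erp_scores))
  colnames(blocks) <- c("dip_x", "dip_y", "dip_z",
                        paste0("topo_pc", seq_len(n_topo_pcs)),
                        paste0("erp_pc", seq_len(n_erp_pcs)))
  structure(list(features = blocks,
                 provenance = brain_ics$provenance,
                 locations = brain_ics$locations,
                 topo_var_captured = sum(topo_pca$sdev[seq_len(n_topo_pcs)]^2) /
                   sum(topo_pca$sdev^2),
                 erp_var_captured = sum(erp_pca$sdev[seq_len(n_erp_pcs)]^2) /
                   sum(erp_pca$sdev^2)),
            class = "ic_features")
}

#' Cluster brain ICs across participants
#'
#' k-means in the 18-dimensional feature space (best of `n_restarts`
#' starts by within-cluster sum of squares), followed by a single
#' outlier-pruning pass (members farther than `outlier_sd` in-cluster
#' distance SDs from their centroid are dropped and the remaining
#' memberships recomputed once against the re-estimated centroids).
#' A cluster is retained only when it contains ICs from strictly more
#' than half of the cohort's participants.  ICs are sorted into a
#' canonical (participant, ic) order first, so the result does not depend
#' on supply order.
#'
#' @param ic_features an `ic_features` object.
#' @param k number of clusters (default 7; choose via the emitted
#'   silhouette diagnostic, no automatic selection is performed).
#' @param n_participants cohort size (for the majority-retention rule).
#' @param outlier_sd pruning threshold in in-cluster distance SDs
#'   (default 3).
#' @param seed integer seed.
#' @param n_restarts k-means restarts (default 20).
#' @return list of class `ic_clusters`: `membership` (data.frame
#'   participant, ic, cluster, outlier), `summary` (per cluster: sizes,
#'   distinct participants, retained flag, centroid dipole location),
#'   `centers` (k x 18), `silhouette` (mean silhouette width).
#' @export
cluster_ics <- function(ic_features, k = 7L, n_participants,
                        outlier_sd = 3, seed = 1L, n_restarts = 20L) {
  k <- check_count(k, "k", min = 2L)
  n_participants <- check_count(n_participants, "n_participants")
  X <- ic_features$features
  if (k >= nrow(X)) stop_invalid("k (%d) must be smaller than the number of ICs (%d)",
                                 k, nrow(X))
  ord <- order(ic_features$provenance$participant, ic_features$provenance$ic)
  X <- X[ord, , drop = FALSE]
  prov <- ic_features$provenance[ord, , drop = FALSE]
  locs <- ic_features$locations[ord, , drop = FALSE]

  rng <- local_rng(derive_seed(seed, 4L))
  on.exit(rng$restore())
  km <- stats::kmeans(X, centers = k, nstart = n_restarts, iter.max = 100L)
  assign0 <- km$cluster

  # one outlier-pruning pass
  dist_to <- function(centers, assign) {
    sqrt(rowSums((X - centers[assign, , drop = FALSE])^2))
  }
  d <- dist_to(km$centers, assign0)
  outlier <- rep(FALSE, nrow(X))
  for (cl in seq_len(k)) {
    ix <- which(assign0 == cl)
    if (length(ix) < 3L) next
    # cluster SD = RMS member distance to centroid (the usual k-means
    # cluster standard deviation); prune members beyond outlier_sd of it
    sdd <- sqrt(mean(d[ix]^2))
    if (sdd > 0) outlier[ix] <- d[ix] > outlier_sd * sdd
  }
  centers <- km$centers
  if (any(outlier)) {
    for (cl in seq_len(k)) {
      ix <- which(assign0 == cl & !outlier)
      if (length(ix) > 0) centers[cl, ] <- colMeans(X[ix, , drop = FALSE])
    }
    # recompute membership once for the surviving ICs
    D <- vapply(seq_len(k), function(cl) {
      rowSums(sweep(X, 2L, centers[cl, ], "-")^2)
    }, numeric(nrow(X)))
    assign1 <- max.col(-D)
    assign1[outlier] <- NA_integer_
  } else {
    assign1 <- assign0
  }

  membership <- data.frame(participant = prov$participant, ic = prov$ic,
                           cluster = assign1, outlier = outlier)
  summary <- do.call(rbind, lapply(seq_len(k), function(cl) {
    ix <- which(assign1 == cl)
    npart <- length(unique(prov$participant[ix]))
    cen <- if (length(ix) > 0) colMeans(locs[ix, , drop = FALSE]) else rep(NA_real_, 3L)
    data.frame(cluster = cl, n_members = length(ix),
               n_participants = npart,
               retained = npart > n_participants / 2,
               centroid_x = cen[1L], centroid_y = cen[2L], centroid_z = cen[3L])
  }))

  sil <- NA_real_
  ok <- !is.na(assign1)
  if (length(unique(assign1[ok])) > 1L) {
    sil <- mean(cluster::silhouette(assign1[ok],
                                    stats::dist(X[ok, , drop = FALSE]))[, 3L])
  }
  structure(list(membership = membership, summary = summary,
                 centers = centers, silhouette = sil, k = k),
            class = "ic_clusters")
}

#' @export
print.ic_clusters <- function(x, ...) {
  cat(sprintf("<ic_clusters> k = %d, %d retained (mean silhouette %.3f)\n",
              x$k, sum(x$summary$retained), x$silhouette))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
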