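#' Fisher z transform and its inverse
#'
#' @param r correlation(s) in (-1, 1).
#' @param z Fisher z value(s).
#' @return transformed values.
#' @export
fisher_z <- function(r) atanh(r)

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending, sets
#' `adjusted_(i) = max_{j <= i} (m - j + 1) * p_(j)` capped at 1,
#' restores the original order, and rejects while `adjusted <= alpha`.
#'
#' @param p p-values in [0, 1].
#' @param alpha familywise significance level (default 0.025: 0.05
#'   halved over the two emotional states per rating axis).
#' @return list with `adjusted` (same order as `p`) and `reject`
#'   (logical).
#' @export
holm_bonferroni <- function(p, alpha = 0.025) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj_sorted <- pmin(1, cummax((m - seq_len(m) + 1L) * p[o]))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Group-level significance of cluster prediction accuracy
#'
#' For each cluster's fold-wise correlations (one per held-out
#' participant): Fisher-z transforms the correlations (clamped away from
#' |r| = 1 with a warning), tests mean z > 0 with a one-tailed one-sample
#' t-test (`t = mean(z) / (sd(z) / sqrt(n))`, sample SD, `n - 1` degrees
#' of freedom), back-transforms the mean z to `mean_r`, and applies the
#' Holm-Bonferroni correction across the clusters of this
#' (axis, state) family.
#'
#' @param outcomes named list of `regression_outcome` tables (one per
#'   cluster) for a single (axis, state) family; names are cluster
#'   labels.
#' @param alpha familywise level (default 0.025).
#' @return data.frame with one row per cluster: `cluster`, `n_folds`,
#'   `mean_r`, `mean_mse`, `t`, `p_raw`, `p_holm`, `significant`.
#' @export
group_significance <- function(outcomes, alpha = 0.025) {
  rows <- lapply(names(outcomes), function(nm) {
    oc <- outcomes[[nm]]
    r <- oc$r[oc$defined]
    if (length(r) < 3L) {
      stop_invalid("cluster %s has fewer than 3 usable folds", nm)
    }
    if (any(abs(r) >= 1)) {
      warning("fold correlation at |r| = 1 clamped for the Fisher transform")
      r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
    }
    z <- fisher_z(r)
    n <- length(z)
    sdz <- stats::sd(z)
    if (sdz == 0) {
      warning("zero variance of Fisher z across folds; p set by sign")
      t <- if (mean(z) > 0) Inf else if (mean(z) < 0) -Inf else 0
      p <- if (mean(z) > 0) 0 else if (mean(z) < 0) 1 else 0.5
    } else {
      t <- mean(z) / (sdz / sqrt(n))
      p <- stats::pt(t, df = n - 1L, lower.tail = FALSE)
    }
    data.frame(cluster = nm, n_folds = n,
               mean_r = fisher_z_inv(mean(z)),
               mean_mse = mean(oc$mse[oc$defined]),
               t = t, p_raw = p)
  })
  out <- do.call(rbind, rows)
  hb <- holm_bonferroni(out$p_raw, alpha)
  out$p_holm <- hb$adjusted
  out$significant <- hb$reject
  out
}

#' Per-band coefficient summary across folds
#'
#' Arithmetic mean and sample SD of each band's fitted coefficient over
#' the usable folds, always in the order theta, alpha, beta, gamma.
#'
#' @param outcome a `regression_outcome` table.
#' @return data.frame with columns `band`, `mean`, `sd`.
#' @export
coefficient_summary <- function(outcome) {
  bands <- band_definitions()$name
  oc <- outcome[outcome$defined, , drop = FALSE]
  data.frame(band = bands,
             mean = vapply(bands, function(b) mean(oc[[b]]), numeric(1)),
             sd = vapply(bands, function(b) stats::sd(oc[[b]]), numeric(1)),
             row.names = NULL)
}
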