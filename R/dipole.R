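#' Precompute a coarse dipole search grid
#'
#' Regular grid of candidate locations with radius at most
#' `0.9 * sphere radius`, together with an orthonormal basis of each
#' candidate's 3-column lead field, so that the residual variance of a
#' topography at every candidate is a single matrix product.
#'
#' @param model a `head_model`.
#' @param step_mm grid spacing (default 10 mm).
#' @return list with `locations` (n x 3) and `Q` (n x channels x 3
#'   orthonormal bases), reusable across topographies.
#' @export
make_dipole_grid <- function(model, step_mm = 10) {
  lim <- 0.9 * model$radius
  ax <- seq(-lim, lim, by = step_mm)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- g[sqrt(rowSums(g^2)) <= lim, , drop = FALSE]
  n_ch <- nrow(model$positions)
  Q <- array(0, c(nrow(g), n_ch, 3L))
  for (i in seq_len(nrow(g))) {
    Q[i, , ] <- qr.Q(qr(lead_field_basis(model, g[i, ])))
  }
  list(locations = g, Q = Q, step_mm = step_mm)
}

# residual variance of topography t at one location (moment solved by
# least squares against the 3-column lead-field basis)
dipole_rv_at <- function(model, location, topo) {
  if (sqrt(sum(location^2)) >= model$radius - 1e-9) {
    return(1 + (sqrt(sum(location^2)) - model$radius) / model$radius)
  }
  G <- lead_field_basis(model, location)
  fit <- qr.fitted(qr(G), topo)
  1 - sum(fit^2) / sum(topo^2)
}

#' Fit an equivalent current dipole to an IC topography
#'
#' Coarse-to-fine search: the residual variance (RV) of the topography is
#' evaluated on an interior grid (the moment solved in closed form at
#' each candidate), and the best candidate is refined by derivative-free
#' simplex search until the location moves by less than `refine_tol`.
#' RV is `1 - ||fitted||^2 / ||topography||^2` in the average-reference
#' space and is invariant to the topography's scale.
#'
#' @param topography average-referenced channel vector (non-zero).
#' @param model a `head_model`.
#' @param grid_step_mm coarse grid spacing (default 10 mm).
#' @param refine_tol stop refining when the location changes by less than
#'   this (default 0.5 mm).
#' @param grid optional precomputed [make_dipole_grid()] result (reused
#'   across many topographies).
#' @param coarse_rv_cutoff topographies whose best grid RV exceeds this
#'   get a single abbreviated refinement round: refinement from a 10-mm
#'   grid improves RV by far less than the margin to the 15% acceptance
#'   threshold, so such components cannot become dipolar.
#' @return object of class `dipole_fit`: `location` (mm), `moment`,
#'   `rv`, `converged`.
#' @export
fit_dipole <- function(topography, model, grid_step_mm = 10,
                       refine_tol = 0.5, grid = NULL,
                       coarse_rv_cutoff = 0.35) {
  topo <- as.numeric(topography)
  if (all(topo == 0)) stop_invalid("zero topography cannot be fit")
  topo <- topo - mean(topo)
  if (is.null(grid)) grid <- make_dipole_grid(model, grid_step_mm)

  # RV at all grid candidates in one sweep
  n_g <- nrow(grid$locations)
  proj <- matrix(0, n_g, 3L)
  for (j in 1:3) proj[, j] <- grid$Q[, , j] %*% topo
  rv_grid <- 1 - rowSums(proj^2) / sum(topo^2)
  best <- which.min(rv_grid)

  loc <- grid$locations[best, ]
  obj <- function(r) dipole_rv_at(model, r, topo)
  converged <- FALSE
  hopeless <- rv_grid[best] > coarse_rv_cutoff
  n_rounds <- if (hopeless) 1L else 6L
  maxit <- if (hopeless) 80L else 200L
  for (round in seq_len(n_rounds)) {
    opt <- stats::optim(loc, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    moved <- sqrt(sum((opt$par - loc)^2))
    loc <- opt$par
    if (moved < refine_tol) { converged <- TRUE; break }
  }
  G <- lead_field_basis(model, loc)
  qrG <- qr(G)
  moment <- qr.coef(qrG, topo)
  rv <- 1 - sum(qr.fitted(qrG, topo)^2) / sum(topo^2)
  structure(list(location = as.numeric(loc), moment = as.numeric(moment),
                 rv = max(0, rv), converged = converged,
                 rv_grid_best = rv_grid[best]),
            class = "dipole_fit")
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf("<dipole_fit> location (%.1f, %.1f, %.1f) mm, RV %.3f%%\n",
              x$location[1], x$location[2], x$location[3], 100 * x$rv))
  invisible(x)
}

#' Select brain ICs from a decomposition
#'
#' Applies the stated, automated stand-ins for the usual visual screen.
#' An IC is kept only if (1) its dipole residual variance is at most
#' `rv_max` (default 15%), (2) the dipole lies inside the brain margin
#' (radius at most `brain_margin` of the sphere radius), (3) the log-log
#' slope of its activation PSD over `psd_slope_band` is non-positive
#' (a rising high-frequency spectrum is muscle-like), and (4) its
#' topography does not concentrate more than `frontal_frac_max` of its
#' energy on the `n_frontal` front-most channels (ocular pattern).
#'
#' @param decomposition a `decomposition` with epoch bookkeeping.
#' @param fits list of `dipole_fit`, one per IC.
#' @param model the `head_model` used for fitting.
#' @param rv_max residual-variance threshold (default 0.15).
#' @param brain_margin fraction of the sphere radius counted as brain
#'   (default 0.9).
#' @param psd_slope_band frequency range (Hz) for the muscle heuristic.
#' @param frontal_frac_max,n_frontal ocular-topography heuristic.
#' @param sampling_rate Hz (default taken from the decomposition).
#' @return data.frame with one row per IC: `ic`, `kept`, `reason`
#'   (`"kept"`, `"rv_exceeds_threshold"`, `"outside_brain"`,
#'   `"artifact_spectrum"` or `"artifact_topography"`), `rv`,
#'   `radius_mm`.
#' @export
select_brain_ics <- function(decomposition, fits, model, rv_max = 0.15,
                             brain_margin = 0.9, psd_slope_band = c(20, 45),
                             frontal_frac_max = 0.6, n_frontal = 4L,
                             sampling_rate = decomposition$sampling_rate) {
  stopifnot(length(fits) == decomposition$rank)
  fr <- frontal_channels(model, n_frontal)
  nfft <- min(round(sampling_rate), ncol(decomposition$activations))
  rows <- lapply(seq_len(decomposition$rank), function(i) {
    f <- fits[[i]]
    rad <- sqrt(sum(f$location^2))
    topo <- decomposition$mixing[, i]
    reason <- "kept"
    if (f$rv > rv_max) {
      reason <- "rv_exceeds_threshold"
    } else if (rad > brain_margin * model$radius) {
      reason <- "outside_brain"
    } else {
      w <- welch_psd(decomposition$activations[i, ], sampling_rate,
                     nfft = nfft, overlap = round(nfft / 4))
      ix <- w$freq >= psd_slope_band[1L] & w$freq <= psd_slope_band[2L] &
        w$psd > 0
      slope <- stats::coef(stats::lm(log(w$psd[ix]) ~ log(w$freq[ix])))[2L]
      if (is.finite(slope) && slope > 0) {
        reason <- "artifact_spectrum"
      } else if (sum(topo[fr]^2) / sum(topo^2) > frontal_frac_max) {
        reason <- "artifact_topography"
      }
    }
    data.frame(ic = i, kept = reason == "kept", reason = reason,
               rv = f$rv, radius_mm = rad)
  })
  do.call(rbind, rows)
}
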