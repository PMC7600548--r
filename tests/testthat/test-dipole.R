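test_that("a noiseless planted dipole is recovered almost exactly", {
  hm <- make_head_model(32)
  grid <- make_dipole_grid(hm)
  loc0 <- c(12, -35, 40)
  m0 <- c(0.4, -0.3, 0.8)
  topo <- lead_field(hm, loc0, m0)
  fit <- fit_dipole(topo, hm, grid = grid)
  expect_lt(fit$rv, 1e-6)
  expect_lt(sqrt(sum((fit$location - loc0)^2)), 2)
  expect_true(fit$converged)
  # the fitted moment reproduces the topography
  G <- icaffect:::lead_field_basis(hm, fit$location)
  expect_equal(as.numeric(G %*% fit$moment), topo, tolerance = 1e-3)
})

test_that("residual variance is invariant to topography scale", {
  hm <- make_head_model(16)
  grid <- make_dipole_grid(hm)
  topo <- lead_field(hm, c(-20, 10, 35), c(1, 1, 0.3)) +
    0.05 * rnorm(16)
  f1 <- fit_dipole(topo, hm, grid = grid)
  f2 <- fit_dipole(-3.7 * topo, hm, grid = grid)
  expect_equal(f1$rv, f2$rv, tolerance = 1e-8)
  expect_equal(f1$location, f2$location, tolerance = 1e-4)
})

test_that("refined fits beat every candidate of a coarse grid", {
  hm <- make_head_model(24)
  set.seed(3)
  coarse <- make_dipole_grid(hm, step_mm = 20)
  for (i in 1:3) {
    topo <- lead_field(hm, runif(3, -30, 30), rnorm(3)) + 0.1 * rnorm(24)
    fit <- fit_dipole(topo, hm, grid = make_dipole_grid(hm, 10))
    rv_coarse <- vapply(seq_len(nrow(coarse$locations)), function(g) {
      icaffect:::dipole_rv_at(hm, coarse$locations[g, ], topo - mean(topo))
    }, numeric(1))
    expect_lte(fit$rv, min(rv_coarse) + 1e-10)
  }
})

test_that("zero topographies are rejected", {
  hm <- make_head_model(16)
  expect_error(fit_dipole(rep(0, 16), hm), "zero topography")
})

fake_decomposition <- function(mixing, fs = 96, n_samples = 960,
                               acts = NULL, seed = 1) {
  set.seed(seed)
  k <- ncol(mixing)
  if (is.null(acts)) acts <- matrix(rnorm(k * n_samples), k)
  structure(list(mixing = mixing, unmixing = NULL, activations = acts,
                 rank = k, sampling_rate = fs),
            class = "decomposition")
}

test_that("selection applies the residual-variance and location rules", {
  hm <- make_head_model(16)
  fs <- 96; n <- 960
  topo_in <- lead_field(hm, c(0, -40, 30), c(0, 0, 1))
  set.seed(2)
  lf <- icaffect:::unit_band_noise(n, which((0:(n / 2)) * fs / n > 0 &
                                              (0:(n / 2)) * fs / n <= 20))
  dec <- fake_decomposition(cbind(topo_in / sqrt(sum(topo_in^2)),
                                  topo_in / sqrt(sum(topo_in^2)),
                                  topo_in / sqrt(sum(topo_in^2))),
                            acts = rbind(lf, lf, lf), fs = fs)
  fits <- list(
    structure(list(location = c(0, -40, 30), rv = 0.20, converged = TRUE),
              class = "dipole_fit"),
    structure(list(location = c(0, -40, 30), rv = 0.001, converged = TRUE),
              class = "dipole_fit"),
    structure(list(location = c(0, 0, 85), rv = 0.01, converged = TRUE),
              class = "dipole_fit"))
  sel <- select_brain_ics(dec, fits, hm)
  expect_equal(sel$reason, c("rv_exceeds_threshold", "kept", "outside_brain"))
  expect_equal(sel$kept, c(FALSE, TRUE, FALSE))
})

test_that("muscle-like rising spectra and ocular topographies are screened out", {
  hm <- make_head_model(16)
  fs <- 96
  n <- 960
  set.seed(7)
  # IC 1: rising high-frequency spectrum (high-passed noise)
  hf <- icaffect:::unit_band_noise(n, which((0:(n / 2)) * fs / n >= 35))
  # IC 2: smooth falling spectrum
  lf <- icaffect:::unit_band_noise(n, which((0:(n / 2)) * fs / n > 0 &
                                              (0:(n / 2)) * fs / n <= 20))
  brainy <- lead_field(hm, c(0, -40, 30), c(0, 0, 1))
  ocular <- lead_field(hm, c(0, 78, -6), c(0, 1, 0))
  frontal_frac <- sum(ocular[icaffect:::frontal_channels(hm, 4)]^2) /
    sum(ocular^2)
  expect_gt(frontal_frac, 0.6)  # construction premise
  dec <- fake_decomposition(cbind(brainy, brainy, ocular),
                            acts = rbind(hf, lf, lf), fs = fs)
  fits <- lapply(list(c(0, -40, 30), c(0, -40, 30), c(0, 70, -6)),
                 function(l) structure(list(location = l, rv = 0.01,
                                            converged = TRUE),
                                       class = "dipole_fit"))
  sel <- select_brain_ics(dec, fits, hm)
  expect_equal(sel$reason,
               c("artifact_spectrum", "kept", "artifact_topography"))
})
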