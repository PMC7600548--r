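# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the lead-field oracle sums the Legendre
# expansion term by term with recurrences, the Holm oracle enumerates the
# step-down procedure literally, and the t/p oracle applies the textbook
# formulas directly.

# Truncated Legendre-series surface potential for a dipole in a
# homogeneous sphere (raw, before average reference).
series_dipole_potential <- function(elec_unit, R, sigma, loc, mom,
                                    nmax = 800L) {
  b <- sqrt(sum(loc^2))
  stopifnot(b > 0, b < R)
  r0 <- loc / b
  x <- b / R
  c_ <- pmin(1, pmax(-1, as.numeric(elec_unit %*% r0)))
  m_r <- sum(mom * r0)
  # tangential factor m_t cos(phi) sin(gamma)
  m_t <- as.numeric(elec_unit %*% mom) - c_ * m_r
  V <- numeric(length(c_))
  Pnm1 <- rep(1, length(c_)); Pn <- c_           # P_0, P_1
  dPnm1 <- rep(0, length(c_)); dPn <- rep(1, length(c_))  # P_0', P_1'
  for (n in seq_len(nmax)) {
    V <- V + (2 * n + 1) / n * x^(n - 1) * (n * m_r * Pn + m_t * dPn)
    Pnp1 <- ((2 * n + 1) * c_ * Pn - n * Pnm1) / (n + 1)
    dPnp1 <- dPnm1 + (2 * n + 1) * Pn   # P'_{n+1} = P'_{n-1} + (2n+1) P_n
    Pnm1 <- Pn; Pn <- Pnp1
    dPnm1 <- dPn; dPn <- dPnp1
  }
  V / (4 * pi * sigma * R^2 * 1e-6)
}

# Literal step-down Holm enumeration: reject the smallest remaining
# p-value while (m - rank + 1) * p <= alpha, then stop.
holm_brute_force <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if ((m - i + 1) * p[o[i]] <= alpha) reject[o[i]] <- TRUE else break
  }
  adjusted <- numeric(m)
  run_max <- 0
  for (i in seq_len(m)) {
    run_max <- max(run_max, (m - i + 1) * p[o[i]])
    adjusted[o[i]] <- min(1, run_max)
  }
  list(adjusted = adjusted, reject = reject)
}

# Direct one-tailed one-sample t on Fisher-z values.
fisher_t_oracle <- function(r) {
  z <- atanh(r)
  n <- length(z)
  t <- mean(z) / (sd(z) / sqrt(n))
  list(z = z, t = t, p = pt(t, df = n - 1, lower.tail = FALSE),
       mean_r = tanh(mean(z)))
}

# Small epoched recording fixture: `n_src` dipolar sources with given
# per-epoch amplitudes mixed through the lead field plus white noise.
make_tiny_recording <- function(n_epochs = 12, n_channels = 16, fs = 64,
                                seconds = 2, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  hm <- make_head_model(n_channels)
  locs <- rbind(c(0, -50, 30), c(30, 20, 40))
  n_samp <- fs * seconds
  mix <- vapply(1:2, function(s) {
    v <- lead_field(hm, locs[s, ], c(0.3, 0.4, 0.87))
    v / max(abs(v))
  }, numeric(n_channels))
  ep <- array(0, c(n_epochs, n_channels, n_samp))
  for (e in seq_len(n_epochs)) {
    src <- rbind(sin(2 * pi * 10 * seq_len(n_samp) / fs + e),
                 rnorm(n_samp))
    ep[e, , ] <- 10 * mix %*% src +
      noise_sd * matrix(rnorm(n_channels * n_samp), n_channels)
  }
  structure(list(participant_id = 1L, epochs = ep, sampling_rate = fs,
                 epoch_stimulus = seq_len(n_epochs),
                 channel_names = hm$channel_names,
                 channel_positions = hm$positions),
            class = "participant_recording")
}

# Fast scaled-down pipeline configuration for structural tests (5
# participants, 40 epochs, 16 channels); not the validation conditions.
tiny_pipeline_config <- function(seed = 1, ...) {
  demo_pipeline_config(
    seed = seed,
    cohort = demo_cohort_config(n_participants = 5L, n_per_quadrant = 10L,
                                n_sessions = 2L,
                                seed = icaffect:::derive_seed(seed, 20L)),
    ...)
}
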