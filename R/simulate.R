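#' Specify a simulated EEG source
#'
#' A source is a fixed dipole (location + moment direction) whose
#' activation is built per epoch from four band-limited oscillations
#' (theta 4-7, alpha 8-13, beta 14-30, gamma 31-45 Hz) riding on a 1/f
#' background.  The log power of each band is linear in the standardized
#' normative rating of the epoch's stimulus, with a separate slope per
#' (band, axis, emotional state), which is the ground-truth effect the
#' downstream regression is meant to recover.  Artifact sources (e.g. an
#' ocular dipole) carry no rating effect and no band oscillations, only a
#' large low-frequency background.
#'
#' @param location dipole location (mm, inside the head sphere).
#' @param moment unit moment direction (3-vector; normalized internally).
#' @param band_baseline named numeric: baseline band power (variance
#'   units) for theta, alpha, beta, gamma.  Zero entries silence a band.
#' @param band_slopes data.frame with columns `band`, `axis`
#'   (valence/arousal), `state` (high/low), `slope`: change in natural-log
#'   band power per standardized rating unit, applied only to epochs in
#'   that state on that axis.
#' @param bg_power total 1/f background power (variance units).
#' @param bg_exponent 1/f spectral exponent.
#' @param bg_range frequency range of the background (Hz); background
#'   energy is placed only at frequency bins outside the four analysis
#'   bands so planted band powers are exact.
#' @param is_artifact flag; artifact sources must have all-zero slopes.
#' @param label informal name.
#' @return an object of class `source_spec`.
#' @export
source_spec <- function(location, moment,
                        band_baseline = c(theta = 1, alpha = 2,
                                          beta = 0.6, gamma = 0.15),
                        band_slopes = NULL,
                        bg_power = 0.4, bg_exponent = 1,
                        bg_range = c(0.5, 45),
                        is_artifact = FALSE,
                        label = "source") {
  moment <- as.numeric(moment)
  moment <- moment / sqrt(sum(moment^2))
  if (is.null(band_slopes)) {
    band_slopes <- data.frame(band = character(), axis = character(),
                              state = character(), slope = numeric())
  }
  stopifnot(all(c("band", "axis", "state", "slope") %in% names(band_slopes)),
            all(is.finite(band_slopes$slope)))
  if (is_artifact && nrow(band_slopes) > 0 && any(band_slopes$slope != 0)) {
    stop_invalid("artifact sources must have all-zero band slopes")
  }
  bands <- c("theta", "alpha", "beta", "gamma")
  bb <- rep(0, 4); names(bb) <- bands
  bb[names(band_baseline)] <- band_baseline
  structure(list(location = as.numeric(location), moment = moment,
                 band_baseline = bb, band_slopes = band_slopes,
                 bg_power = bg_power, bg_exponent = bg_exponent,
                 bg_range = bg_range, is_artifact = is_artifact,
                 label = label),
            class = "source_spec")
}

#' Convenience constructor for a band-slope table
#' @param band,axis,state,slope vectors recycled to equal length.
#' @export
band_slope <- function(band, axis, state, slope) {
  data.frame(band = band, axis = axis, state = state, slope = slope,
             stringsAsFactors = FALSE)
}

#' Default planted sources for the demonstration cohorts
#'
#' Four cortical dipoles at well-separated locations plus one shallow
#' frontal ocular dipole.  The occipital source carries a negative theta
#' slope for valence in the high-valence state and the right-parietal
#' source a negative alpha slope for arousal in the high-arousal state;
#' the two remaining cortical sources are null.  Slope magnitude 0.5 is a
#' calibration choice (no physical-unit effect sizes exist to copy) large
#' enough that recovery is a property of the pipeline, not of luck.
#'
#' @param slope planted slope magnitude (default 0.5).
#' @return list of `source_spec` objects.
#' @export
default_sources <- function(slope = 0.5) {
  list(
    source_spec(c(0, -56, 27), c(0.2, -0.5, 0.84),
                band_slopes = band_slope("theta", "valence", "high", -slope),
                label = "occipital"),
    source_spec(c(34, -34, 43), c(0.8, 0.5, 0.33),
                band_slopes = band_slope("alpha", "arousal", "high", -slope),
                label = "right-parietal"),
    source_spec(c(-40, 0, 49), c(-0.7, 0.4, 0.59), label = "left-central"),
    # fronto-central rather than far-frontal, so a sparse montage can
    # still tell it apart from the ocular dipole below
    source_spec(c(0, 30, 57), c(0.3, 0.6, 0.74), label = "fronto-central"),
    # ocular: no band oscillations, large slow (0.5-3.5 Hz) power so the
    # frontal channels see roughly twice the cortical amplitude
    source_spec(c(0, 78, -8), c(0, 0.995, -0.1),
                band_baseline = c(theta = 0, alpha = 0, beta = 0, gamma = 0),
                bg_power = 16, bg_exponent = 1.5, bg_range = c(0.5, 3.5),
                is_artifact = TRUE, label = "ocular")
  )
}

#' Cohort simulation configuration
#'
#' Assembles all generator parameters with the study-design defaults:
#' 25 participants, 160 stimuli (40 per quadrant) over 8 sessions of 20
#' trials, 64 channels, 6-s epochs at 512 Hz, the default source set, and
#' sensor SNR 10.  `demo_cohort_config()` is the scaled-down variant used
#' by the worked examples and the validation runs: 6 participants,
#' 16 channels, 96 Hz (the lowest rate that still resolves the 31-45 Hz
#' gamma band), same 160-epoch design.
#'
#' @param n_participants cohort size.
#' @param n_per_quadrant stimuli per circumplex quadrant.
#' @param n_sessions sessions per participant.
#' @param n_channels electrode count.
#' @param sampling_rate Hz.
#' @param epoch_seconds epoch duration (s).
#' @param sources list of `source_spec`.
#' @param snr ratio of mixed source-signal variance to sensor-noise
#'   variance per channel; must be positive.
#' @param sigma_power SD of the per-epoch noise on log band power.
#' @param jitter_sd_mm SD of per-participant dipole-location jitter.
#' @param slope_jitter_sd SD of the per-participant multiplicative
#'   effect-size perturbation (fraction of slope).
#' @param offset_sd SD of per-participant log band-power offsets.
#' @param noise_white_frac fraction of sensor-noise power that is white
#'   (remainder is 1/f pink).
#' @param source_gain scalp calibration: each source's dipole moment
#'   magnitude is set so that its strongest electrode sees `source_gain`
#'   microvolts per unit of source RMS (topography shapes are untouched).
#'   The default puts cortical channels near 10 uV RMS, the conventional
#'   EEG scale the cleaning thresholds assume.
#' @param burst_env_hz bandwidth (Hz) of the slow random envelope that
#'   burst-modulates every band oscillation (0 disables).  Bursting makes
#'   the sources super-Gaussian, as real EEG rhythms are; it costs a
#'   small, nearly constant in-band energy fraction (about 0.91 at the
#'   default), which standardization absorbs.
#' @param radius_mm,conductivity head-model parameters.
#' @param seed base seed for the whole cohort.
#' @param keep_ground_truth store planted per-epoch log band powers and
#'   mixing in each recording.
#' @param keep_source_signals additionally store raw source activations
#'   (memory-heavy; used by oracle checks).
#' @return a config list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 25L, n_per_quadrant = 40L,
                          n_sessions = 8L, n_channels = 64L,
                          sampling_rate = 512, epoch_seconds = 6,
                          sources = default_sources(), snr = 10,
                          sigma_power = 0.25, jitter_sd_mm = 5,
                          slope_jitter_sd = 0.2, offset_sd = 0.3,
                          noise_white_frac = 0.5, source_gain = 5,
                          burst_env_hz = 0.5,
                          radius_mm = 90, conductivity = 0.33,
                          seed = 1L, keep_ground_truth = TRUE,
                          keep_source_signals = FALSE) {
  if (snr <= 0) stop_invalid("`snr` must be positive")
  if (!any(!vapply(sources, `[[`, TRUE, "is_artifact"))) {
    stop_invalid("at least one non-artifact source is required")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
demo_cohort_config <- function(n_participants = 6L, n_channels = 16L,
                               sampling_rate = 96, seed = 1L, ...) {
  cohort_config(n_participants = n_participants, n_channels = n_channels,
                sampling_rate = sampling_rate, seed = seed, ...)
}

#' Simulate a multi-participant EEG cohort with planted effects
#'
#' Generates, for every participant, epoched scalp EEG by mixing the
#' configured dipolar sources through the spherical-head lead field and
#' adding sensor noise at the configured SNR.  For each epoch e and source
#' s, the realized log power of band b equals
#' `log(baseline_b) + slope(b, axis, state(e)) * z(e) + offset + noise`,
#' where z(e) is the stimulus rating standardized over the stimulus set --
#' exact by construction (oscillations are synthesized with fixed
#' amplitude spectra and random phases, and background energy avoids the
#' band bins) up to the small, nearly constant spectral leakage of the
#' burst envelope, so downstream stages can be scored against ground
#' truth.
#'
#' @param config a `cohort_config`.
#' @return an object of class `eeg_cohort`: list with `stimuli`,
#'   `head_model`, `config` and `participants` (each a
#'   `participant_recording` with `epochs` (trials x channels x samples),
#'   `sampling_rate`, `schedule`, `epoch_stimulus` and `ground_truth`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  stim <- generate_stimulus_set(cf$n_per_quadrant, seed = derive_seed(cf$seed, 10L))
  hm <- make_head_model(cf$n_channels, cf$radius_mm, cf$conductivity)
  zval <- as.numeric(scale_pop(matrix(stim$valence)))
  zaro <- as.numeric(scale_pop(matrix(stim$arousal)))

  participants <- lapply(seq_len(cf$n_participants), function(p) {
    simulate_participant(p, cf, stim, hm, zval, zaro,
                         seed = derive_seed(cf$seed, 100L + p))
  })
  structure(list(stimuli = stim, head_model = hm, config = cf,
                 participants = participants),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  d <- dim(x$participants[[1L]]$epochs)
  cat(sprintf(
    "<eeg_cohort> %d participants, %d epochs x %d channels x %d samples @ %g Hz\n",
    length(x$participants), d[1L], d[2L], d[3L],
    x$participants[[1L]]$sampling_rate))
  invisible(x)
}

simulate_participant <- function(p, cf, stim, hm, zval, zaro, seed) {
  rng <- local_rng(seed)
  on.exit(rng$restore())

  fs <- cf$sampling_rate
  n_samp <- as.integer(round(cf$epoch_seconds * fs))
  sched <- generate_schedule(stim, cf$n_sessions, seed = seed)
  epoch_stim <- sched$stimulus_id
  n_ep <- length(epoch_stim)
  n_src <- length(cf$sources)
  bands <- band_definitions()
  gain <- cf$source_gain

  # per-participant source-location jitter; cortical sources are kept at
  # depths where single-dipole localization is well conditioned, artifact
  # sources may sit shallower
  locs <- lapply(cf$sources, function(s) {
    loc <- s$location + stats::rnorm(3, 0, cf$jitter_sd_mm)
    r <- sqrt(sum(loc^2))
    lim <- (if (s$is_artifact) 0.88 else 0.80) * hm$radius
    if (r > lim) loc <- loc * lim / r
    loc
  })
  mixing <- vapply(seq_len(n_src), function(s) {
    col <- lead_field(hm, locs[[s]], cf$sources[[s]]$moment)
    col / max(abs(col))  # moment magnitude calibrated to the scalp scale
  }, numeric(cf$n_channels))
  slope_mult <- stats::rnorm(n_src, 1, cf$slope_jitter_sd)
  band_offset <- matrix(stats::rnorm(n_src * 4L, 0, cf$offset_sd), n_src, 4L)

  # planted per-epoch log band power, per source
  log_bp <- array(-Inf, c(n_ep, n_src, 4L),
                  dimnames = list(NULL, NULL, bands$name))
  for (s in seq_len(n_src)) {
    src <- cf$sources[[s]]
    for (b in seq_len(4L)) {
      base <- src$band_baseline[[bands$name[b]]]
      if (base <= 0) next
      lp <- rep(log(base), n_ep) + band_offset[s, b]
      sl <- src$band_slopes
      sl <- sl[sl$band == bands$name[b], , drop = FALSE]
      if (nrow(sl) > 0) {
        for (i in seq_len(nrow(sl))) {
          z <- if (sl$axis[i] == "valence") zval[epoch_stim] else zaro[epoch_stim]
          raw <- if (sl$axis[i] == "valence") stim$valence[epoch_stim] else stim$arousal[epoch_stim]
          in_state <- if (sl$state[i] == "high") raw > 5 else raw < 5
          lp <- lp + ifelse(in_state, sl$slope[i] * slope_mult[s] * z, 0)
        }
      }
      lp <- lp + stats::rnorm(n_ep, 0, cf$sigma_power)
      log_bp[, s, b] <- lp
    }
  }

  # spectral bin bookkeeping for the epoch length
  freq <- (0:(n_samp %/% 2L)) * fs / n_samp
  band_bins <- lapply(seq_len(4L), function(b) {
    which(freq >= bands$lo[b] & freq <= bands$hi[b])
  })
  in_any_band <- Reduce(`|`, lapply(band_bins, function(ix) {
    seq_along(freq) %in% ix
  }))

  # source activations, synthesized band by band across all epochs at once
  src_act <- array(0, c(n_src, n_samp, n_ep))
  for (s in seq_len(n_src)) {
    src <- cf$sources[[s]]
    acc <- matrix(0, n_samp, n_ep)
    for (b in seq_len(4L)) {
      lp <- log_bp[, s, b]
      if (all(!is.finite(lp))) next
      u <- band_noise_matrix(n_samp, band_bins[[b]], n_cols = n_ep)
      if (cf$burst_env_hz > 0) {
        # burst-amplitude modulation: EEG oscillations wax and wane, which
        # also gives the super-Gaussian marginals ICA identification needs
        env_bins <- which(freq > 0 & freq <= cf$burst_env_hz)
        g <- band_noise_matrix(n_samp, env_bins, n_cols = n_ep)
        u <- u * g^2
        u <- sweep(u, 2L, sqrt(colMeans(u^2)), "/")
      }
      acc <- acc + u * rep(sqrt(exp(lp)), each = n_samp)
    }
    bg_bins <- which(freq >= src$bg_range[1L] & freq <= src$bg_range[2L] &
                       !in_any_band)
    if (length(bg_bins) && src$bg_power > 0) {
      a <- freq[bg_bins]^(-src$bg_exponent / 2)
      acc <- acc + sqrt(src$bg_power) *
        band_noise_matrix(n_samp, bg_bins, amp = a, n_cols = n_ep)
    }
    src_act[s, , ] <- acc
  }

  # mix through the lead field; sensor noise (white + pink) at target SNR
  mixed <- (gain * mixing) %*% matrix(src_act, n_src, n_samp * n_ep)
  sig_var <- mean(apply(mixed, 1L, stats::var))
  noise_sd <- sqrt(sig_var / cf$snr)
  wf <- cf$noise_white_frac
  noise <- sqrt(wf) * matrix(stats::rnorm(length(mixed)), nrow(mixed))
  pink_bins <- which(freq >= 0.5 & freq <= min(45, fs / 2))
  pink_amp <- freq[pink_bins]^(-0.5)
  pk <- band_noise_matrix(n_samp, pink_bins, amp = pink_amp,
                          n_cols = cf$n_channels * n_ep)
  noise <- noise + sqrt(1 - wf) *
    matrix(aperm(array(pk, c(n_samp, cf$n_channels, n_ep)), c(2L, 1L, 3L)),
           cf$n_channels, n_samp * n_ep)
  mixed <- mixed + noise_sd * noise
  epochs <- aperm(array(mixed, c(cf$n_channels, n_samp, n_ep)), c(3L, 1L, 2L))

  gt <- NULL
  if (isTRUE(cf$keep_ground_truth)) {
    gt <- list(source_locations = do.call(rbind, locs),
               mixing = gain * mixing,
               log_band_power = log_bp,
               slope_mult = slope_mult,
               is_artifact = vapply(cf$sources, `[[`, TRUE, "is_artifact"),
               z_valence = zval[epoch_stim],
               z_arousal = zaro[epoch_stim])
    if (isTRUE(cf$keep_source_signals)) {
      gt$source_signals <- aperm(src_act, c(1L, 3L, 2L))  # src x epoch x sample
    }
  }
  structure(list(participant_id = p, epochs = epochs, sampling_rate = fs,
                 schedule = sched, epoch_stimulus = epoch_stim,
                 channel_names = hm$channel_names,
                 channel_positions = hm$positions,
                 ground_truth = gt),
            class = "participant_recording")
}

# Band-limited unit-RMS noise: fixed amplitude spectrum on the given rfft
# bins, uniform random phases, exact unit power after synthesis.
unit_band_noise <- function(n, bins, amp = NULL) {
  band_noise_matrix(n, bins, amp, n_cols = 1L)[, 1L]
}

# Matrix of independent band-limited unit-RMS noise columns (batch
# synthesis via one inverse mvfft).
band_noise_matrix <- function(n, bins, amp = NULL, n_cols = 1L) {
  half <- n %/% 2L
  if (is.null(amp)) amp <- rep(1, length(bins))
  spec <- matrix(complex(real = 0), half + 1L, n_cols)
  ph <- matrix(stats::runif(length(bins) * n_cols, 0, 2 * pi),
               length(bins), n_cols)
  spec[bins, ] <- amp * exp(1i * ph)
  full <- rbind(spec, Conj(spec[half:2, , drop = FALSE]))
  x <- Re(stats::mvfft(full, inverse = TRUE)) / n
  rms <- sqrt(colMeans(x^2))
  rms[rms == 0] <- 1
  sweep(x, 2L, rms, "/")
}
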