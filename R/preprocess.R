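#' Design a windowed-sinc FIR filter
#'
#' Hamming-windowed sinc design via [signal::fir1()], with the order
#' chosen from the transition width (approximately `3.3 * fs / width`
#' taps, rounded up to even so the group delay is integer).
#'
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency.
#' @param type `"high"` or `"low"`.
#' @param transition_hz transition-band width (defaults: 0.5 Hz for
#'   high-pass, 5 Hz for low-pass).
#' @return numeric vector of filter coefficients (odd length).
#' @keywords internal
design_fir <- function(fs, cutoff_hz, type = c("high", "low"),
                       transition_hz = if (type == "high") 0.5 else 5) {
  type <- match.arg(type)
  if (cutoff_hz >= fs / 2) {
    stop_invalid("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, fs / 2)
  }
  n <- ceiling(3.3 * fs / transition_hz)
  if (n %% 2L == 1L) n <- n + 1L  # even order -> odd length, integer delay
  as.numeric(signal::fir1(n, cutoff_hz / (fs / 2), type))
}

# Linear-phase FIR applied by FFT convolution with group-delay
# compensation; x is a channels x samples matrix.  Edge effects are
# confined to one filter length at each end.
apply_fir <- function(x, h) {
  x <- rbind(x)
  n <- ncol(x)
  L <- length(h)
  d <- (L - 1L) %/% 2L
  nfft <- stats::nextn(n + L - 1L, 2L)
  H <- stats::fft(c(h, rep(0, nfft - L)))
  out <- t(apply(x, 1L, function(ch) {
    y <- Re(stats::fft(stats::fft(c(ch, rep(0, nfft - n))) * H,
                       inverse = TRUE)) / nfft
    y[(d + 1L):(d + n)]  # compensate the linear-phase delay
  }))
  dimnames(out) <- dimnames(x)
  out
}

#' Band-pass filter and downsample a continuous recording
#'
#' The standard acquisition chain: optional re-reference, zero-lag
#' high-pass FIR at 0.5 Hz and low-pass FIR at 45 Hz (windowed-sinc,
#' Hamming window, linear phase with delay compensation), then decimation
#' to the target rate.  The 45-Hz low-pass doubles as the anti-aliasing
#' filter for any target rate of 96 Hz or more.
#'
#' @param recording list with `data` (channels x samples matrix),
#'   `sampling_rate`, and optionally `reference_data` (2 x samples earlobe
#'   signals).
#' @param highpass_hz,lowpass_hz FIR cutoffs (Hz).
#' @param target_rate_hz output rate; must divide the input rate.
#' @param reference `"earlobe-average"` (requires `reference_data`),
#'   `"average"`, or `"none"`.
#' @return the recording with filtered, decimated `data` and updated
#'   `sampling_rate`.
#' @export
preprocess_raw <- function(recording, highpass_hz = 0.5, lowpass_hz = 45,
                           target_rate_hz = 512,
                           reference = c("earlobe-average", "average", "none")) {
  reference <- match.arg(reference)
  fs <- recording$sampling_rate
  x <- recording$data
  if (highpass_hz >= fs / 2 || lowpass_hz >= fs / 2) {
    stop_invalid("filter cutoffs must be below the Nyquist frequency (%g Hz)",
                 fs / 2)
  }
  if (fs %% target_rate_hz != 0) {
    stop_invalid("target rate (%g Hz) must divide the source rate (%g Hz)",
                 target_rate_hz, fs)
  }
  if (lowpass_hz > target_rate_hz / 2) {
    stop_invalid("low-pass cutoff (%g Hz) exceeds the target Nyquist (%g Hz)",
                 lowpass_hz, target_rate_hz / 2)
  }
  x <- switch(reference,
    "earlobe-average" = {
      if (is.null(recording$reference_data)) {
        stop_invalid("earlobe-average reference requires `reference_data`")
      }
      sweep(x, 2L, colMeans(rbind(recording$reference_data)), "-")
    },
    "average" = sweep(x, 2L, colMeans(x), "-"),
    "none" = x)
  x <- apply_fir(x, design_fir(fs, highpass_hz, "high"))
  x <- apply_fir(x, design_fir(fs, lowpass_hz, "low"))
  dec <- as.integer(fs / target_rate_hz)
  if (dec > 1L) x <- x[, seq(1L, ncol(x), by = dec), drop = FALSE]
  recording$data <- x
  recording$sampling_rate <- target_rate_hz
  recording$reference <- reference
  recording
}

#' Cut a continuous recording into fixed-length epochs
#'
#' @param data channels x samples matrix.
#' @param onsets epoch onset sample indices (1-based).
#' @param n_samples epoch length in samples.
#' @return epochs x channels x samples array.
#' @export
extract_epochs <- function(data, onsets, n_samples) {
  n_samples <- check_count(n_samples, "n_samples")
  if (any(onsets < 1L) || any(onsets + n_samples - 1L > ncol(data))) {
    stop_invalid("epoch window extends beyond the recording")
  }
  out <- array(0, c(length(onsets), nrow(data), n_samples))
  for (e in seq_along(onsets)) {
    out[e, , ] <- data[, onsets[e]:(onsets[e] + n_samples - 1L)]
  }
  out
}

#' Automated channel and epoch cleaning
#'
#' Replaces the visual-inspection step with stated criteria: channels
#' whose robust z-score of log variance exceeds `channel_z_thresh` (in
#' absolute value, catching both noisy and dead channels) are flagged and
#' interpolated by spherical-spline interpolation; epochs whose
#' peak-to-peak amplitude exceeds `epoch_ptp_thresh` or whose robust
#' log-variance z-score exceeds `epoch_z_thresh` are removed.  Unflagged
#' channels and epochs are never altered.
#'
#' @param recording a `participant_recording` (or any list with `epochs`
#'   array, `channel_positions`, `epoch_stimulus`).
#' @param channel_z_thresh robust-z threshold for channel rejection
#'   (default 5).
#' @param epoch_ptp_thresh peak-to-peak rejection threshold in signal
#'   units (default 200, the conventional microvolt bound).
#' @param epoch_z_thresh robust-z threshold for epoch variance (default 4).
#' @return the recording with cleaned `epochs`, updated `epoch_stimulus`,
#'   a logical `interpolated` channel flag, and a `cleaning_report` with
#'   the counts and identities of everything touched.
#' @export
clean_epochs <- function(recording, channel_z_thresh = 5,
                         epoch_ptp_thresh = 200, epoch_z_thresh = 4) {
  ep <- recording$epochs
  n_ep <- dim(ep)[1L]; n_ch <- dim(ep)[2L]
  if (n_ep < 2L) stop_invalid("need at least 2 epochs")

  ch_var <- vapply(seq_len(n_ch), function(ch) stats::var(as.numeric(ep[, ch, ])),
                   numeric(1))
  zch <- robust_z(log(pmax(ch_var, .Machine$double.xmin)))
  bad_ch <- which(abs(zch) > channel_z_thresh)
  if (length(bad_ch) >= n_ch - 3L) {
    stop_invalid("fewer than 4 good channels remain after channel rejection")
  }
  if (length(bad_ch) > 0) {
    w <- interp_weights(recording$channel_positions, bad_ch)
    for (e in seq_len(n_ep)) {
      ep[e, bad_ch, ] <- w %*% ep[e, -bad_ch, , drop = TRUE]
    }
  }

  ptp <- vapply(seq_len(n_ep), function(e) {
    max(apply(ep[e, , , drop = TRUE], 1L, function(v) diff(range(v))))
  }, numeric(1))
  ep_var <- vapply(seq_len(n_ep), function(e) mean(apply(ep[e, , , drop = TRUE], 1L, stats::var)),
                   numeric(1))
  zep <- robust_z(log(pmax(ep_var, .Machine$double.xmin)))
  bad_ep <- which(ptp > epoch_ptp_thresh | zep > epoch_z_thresh)
  if (length(bad_ep) == n_ep) {
    stop_invalid("pipeline abort: all %d epochs rejected (ptp range %.3g-%.3g)",
                 n_ep, min(ptp), max(ptp))
  }
  keep <- setdiff(seq_len(n_ep), bad_ep)

  recording$epochs <- ep[keep, , , drop = FALSE]
  recording$epoch_stimulus <- recording$epoch_stimulus[keep]
  recording$interpolated <- seq_len(n_ch) %in% bad_ch
  recording$cleaning_report <- list(
    n_channels_interpolated = length(bad_ch),
    channels_interpolated = bad_ch,
    n_epochs_removed = length(bad_ep),
    fraction_epochs_removed = length(bad_ep) / n_ep,
    epochs_removed = bad_ep,
    kept_epochs = keep)
  recording
}

robust_z <- function(x) {
  med <- stats::median(x)
  madv <- stats::mad(x)
  if (madv == 0) return(rep(0, length(x)))
  (x - med) / madv
}

# Spherical-spline interpolation weights (Perrin-style, m = 4, Legendre
# order 7, light ridge regularization): rows = bad channels, cols = good
# channels.  Distance-based averaging mis-handles average-referenced
# fields whose distant channels carry opposite polarity; the spline
# respects the field's smooth spatial structure.
interp_weights <- function(positions, bad, m = 4L, n_legendre = 7L,
                           lambda = 1e-5) {
  good <- setdiff(seq_len(nrow(positions)), bad)
  n_g <- length(good)
  g_fun <- function(x) {
    # g(x) = (1/4pi) sum (2n+1) / (n (n+1))^m  P_n(x)
    out <- 0
    Pnm1 <- rep(1, length(x)); Pn <- x
    for (n in seq_len(n_legendre)) {
      out <- out + (2 * n + 1) / (n * (n + 1))^m * Pn
      Pnp1 <- ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
      Pnm1 <- Pn; Pn <- Pnp1
    }
    out / (4 * pi)
  }
  cos_gg <- tcrossprod(positions[good, , drop = FALSE])
  G <- matrix(g_fun(pmin(1, pmax(-1, cos_gg))), n_g) + lambda * diag(n_g)
  M <- rbind(cbind(G, 1), c(rep(1, n_g), 0))
  Minv <- solve(M)
  w <- matrix(0, length(bad), n_g)
  for (i in seq_along(bad)) {
    cb <- pmin(1, pmax(-1, positions[good, , drop = FALSE] %*%
                         positions[bad[i], ]))
    w[i, ] <- c(g_fun(as.numeric(cb)), 1) %*% Minv[, seq_len(n_g)]
  }
  w
}

#' Concatenate cleaned epochs and reduce to rank for ICA
#'
#' Concatenates epochs along time, applies the common-average reference,
#' and projects the data onto its top-`rank` principal subspace, where
#' `rank = n_channels - 1 - n_interpolated` (one dimension lost to the
#' average reference, one per interpolated channel).
#'
#' @param recording a cleaned `participant_recording`.
#' @return list of class `ica_ready`: `data` (channels x total samples,
#'   rank-reduced, average-referenced), `rank`, `basis` (channels x rank
#'   principal directions), `n_epochs`, `samples_per_epoch`,
#'   `sampling_rate`, `epoch_stimulus`, `channel_positions`.
#' @export
prepare_for_ica <- function(recording) {
  ep <- recording$epochs
  n_ep <- dim(ep)[1L]; n_ch <- dim(ep)[2L]; n_samp <- dim(ep)[3L]
  x <- matrix(aperm(ep, c(2L, 3L, 1L)), n_ch, n_samp * n_ep)
  x <- sweep(x, 2L, colMeans(x), "-")  # average reference
  n_interp <- sum(recording$interpolated %||% logical(n_ch))
  rank <- n_ch - 1L - n_interp
  if (rank < 4L) stop_invalid("pipeline abort: data rank %d < 4", rank)
  sv <- svd(x, nu = rank, nv = 0L)
  basis <- sv$u
  x_r <- basis %*% (t(basis) %*% x)
  structure(list(data = x_r, rank = rank, basis = basis,
                 n_epochs = n_ep, samples_per_epoch = n_samp,
                 sampling_rate = recording$sampling_rate,
                 epoch_stimulus = recording$epoch_stimulus,
                 channel_positions = recording$channel_positions),
            class = "ica_ready")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
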