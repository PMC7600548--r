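#' Frequency band definitions
#'
#' The four analysis bands: theta 4-7, alpha 8-13, beta 14-30 and gamma
#' 31-45 Hz.  Band edges are inclusive at both ends; with the default
#' 1-Hz spectral resolution the boundary bins matter (7 Hz belongs to
#' theta, 8 Hz to alpha).
#'
#' @return data.frame with columns `name`, `lo`, `hi`.
#' @export
band_definitions <- function() {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             lo = c(4, 8, 14, 31), hi = c(7, 13, 30, 45),
             stringsAsFactors = FALSE)
}

#' Welch power spectral density
#'
#' Segment-averaged one-sided periodogram: segments of `nfft` samples
#' advanced by `nfft - overlap`, Hann-windowed and window-power
#' normalized.  The defaults (512-point FFT, 128-point overlap) give 1-Hz
#' resolution and 7 averaged segments on a 6-s epoch at 512 Hz; at other
#' sampling rates callers keep the same 1-s window by passing
#' `nfft = fs`, `overlap = fs / 4`.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param nfft segment length in samples.
#' @param overlap overlap between consecutive segments in samples.
#' @return list with `freq` (Hz) and `psd` (power per Hz) such that
#'   `sum(psd) * fs / nfft` approximates the signal variance.
#' @examples
#' w <- welch_psd(sin(2 * pi * 10 * (0:3071) / 512), fs = 512)
#' w$freq[which.max(w$psd)]
#' @export
welch_psd <- function(x, fs, nfft = 512L, overlap = 128L) {
  x <- as.numeric(x)
  nfft <- check_count(nfft, "nfft", min = 8L)
  overlap <- check_count(overlap, "overlap", min = 0L)
  if (overlap >= nfft) stop_invalid("`overlap` must be smaller than `nfft`")
  if (length(x) < nfft) {
    stop_invalid("signal (%d samples) is shorter than nfft (%d)",
                 length(x), nfft)
  }
  step <- nfft - overlap
  n_seg <- (length(x) - nfft) %/% step + 1L
  half <- nfft %/% 2L
  pxx <- welch_psd_matrix(matrix(x), fs, nfft, overlap)[, 1L]
  list(freq = (0:half) * fs / nfft, psd = pxx, n_segments = n_seg)
}

# Batch Welch: columns of `x` are independent signals; returns a
# (nfft/2 + 1) x ncol(x) matrix of one-sided PSDs.
welch_psd_matrix <- function(x, fs, nfft, overlap) {
  n <- nrow(x)
  step <- nfft - overlap
  n_seg <- (n - nfft) %/% step + 1L
  w <- hann_window(nfft)
  u <- sum(w^2)
  starts <- (seq_len(n_seg) - 1L) * step
  idx <- as.vector(outer(seq_len(nfft), starts, "+"))  # nfft x n_seg
  seg <- matrix(x[idx, , drop = FALSE] * w, nfft, n_seg * ncol(x))
  sp <- stats::mvfft(seg)
  half <- nfft %/% 2L
  p <- Mod(sp[1:(half + 1L), , drop = FALSE])^2 / (fs * u)
  p <- array(p, c(half + 1L, n_seg, ncol(x)))
  pxx <- colMeans(aperm(p, c(2L, 1L, 3L)))  # average over segments
  pxx[2:half, ] <- 2 * pxx[2:half, ]  # one-sided (DC, Nyquist not doubled)
  pxx
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
}

#' Band power from a PSD
#'
#' Band power is the mean of the PSD bins with `lo <= f <= hi`
#' (inclusive at both edges).  With fixed 1-Hz bins this differs from the
#' band integral only by a constant per band, which the later
#' per-participant standardization removes.
#'
#' @param psd,freq as returned by [welch_psd()].
#' @param bands band table (default [band_definitions()]).
#' @return named numeric vector of band powers.
#' @export
band_power <- function(psd, freq, bands = band_definitions()) {
  out <- vapply(seq_len(nrow(bands)), function(b) {
    ix <- freq >= bands$lo[b] & freq <= bands$hi[b]
    if (!any(ix)) return(NA_real_)
    mean(psd[ix])
  }, numeric(1))
  names(out) <- bands$name
  out
}

#' Per-epoch log band-power features for one IC cluster
#'
#' For every participant contributing to the cluster and every epoch,
#' computes the Welch PSD of each member IC's activation in that epoch,
#' averages the PSDs bin-wise across the participant's member ICs (PSD
#' averaging happens *before* the logarithm), extracts the four band
#' powers, and returns their natural logarithms linked to the epoch's
#' stimulus.
#'
#' @param members data.frame with columns `participant`, `ic` listing the
#'   cluster's member ICs.
#' @param activations named list (by participant id as character) of
#'   3-d arrays `ics x epochs x samples` of IC activations.
#' @param epoch_stimulus named list (same names) of per-epoch stimulus
#'   ids.
#' @param fs sampling rate (Hz).
#' @param nfft,overlap Welch parameters (defaults follow the 1-s window
#'   convention: `nfft = fs`, `overlap = fs / 4`).
#' @param bands band table.
#' @return data.frame with columns `participant`, `epoch`, `stimulus_id`,
#'   `theta`, `alpha`, `beta`, `gamma` (natural-log band power).
#' @export
aggregate_cluster_features <- function(members, activations, epoch_stimulus,
                                       fs, nfft = round(fs), overlap = round(fs / 4),
                                       bands = band_definitions()) {
  stopifnot(all(c("participant", "ic") %in% names(members)))
  out <- list()
  for (p in unique(members$participant)) {
    ics <- members$ic[members$participant == p]
    act <- activations[[as.character(p)]]
    stim <- epoch_stimulus[[as.character(p)]]
    n_ep <- dim(act)[2L]
    half <- round(nfft) %/% 2L
    freq <- (0:half) * fs / round(nfft)
    psum <- matrix(0, half + 1L, n_ep)
    for (ic in ics) {
      psum <- psum + welch_psd_matrix(t(act[ic, , , drop = TRUE]), fs,
                                      round(nfft), round(overlap))
    }
    pavg <- psum / length(ics)  # PSDs averaged across member ICs first
    bp <- t(vapply(seq_len(nrow(bands)), function(b) {
      colMeans(pavg[freq >= bands$lo[b] & freq <= bands$hi[b], , drop = FALSE])
    }, numeric(n_ep)))
    bp <- t(bp)
    if (any(bp <= 0, na.rm = TRUE)) {
      stop_invalid("non-positive band power encountered (degenerate signal)")
    }
    df <- data.frame(participant = p, epoch = seq_len(n_ep),
                     stimulus_id = stim)
    df[bands$name] <- log(bp)
    out[[length(out) + 1L]] <- df
  }
  do.call(rbind, out)
}
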